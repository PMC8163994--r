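---
title: "Along-tract profiling and permutation statistics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Along-tract profiling and permutation statistics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tractoprofile)
```

## What the package computes

`tractoprofile` implements along-tract ("tractometry") analysis of
white-matter fiber bundles. A bundle is a set of streamlines (3D polylines
in world-space mm, read from TCK files or generated synthetically). For
each bundle the package:

1. builds a **100-segment along-tract coordinate system** from the bundle's
   centroid fiber;
2. evaluates one of three microstructural metrics along every streamline —
   **apparent fiber density** (AFD, the integral of one lobe of the fiber
   orientation distribution), the **FOD peak amplitude**, or the
   tensor-derived **fractional anisotropy** (FA) — and averages the values
   per segment into a subject profile;
3. compares two groups of subjects per bundle and per segment with a
   permutation-corrected t-test family (maxT family-wise error control),
   cluster-extent filtering, Cohen's *d*, post-hoc power, and semi-partial
   cofactor correlations.

A synthetic-cohort generator produces bundles, spherical-harmonic FOD
volumes, tensor volumes and two-group cohort tables with localized injected
effects, so every stage is testable without MRI data.

## The along-tract coordinate system

The **centroid fiber** of a bundle is the member streamline minimizing the
mean flip-invariant corresponding-point distance to all others: every
streamline is resampled to 101 equally spaced (arc-length) points, the
distance between two streamlines is the mean of pointwise Euclidean
distances minimized over direct and reversed orderings, and the winner (ties:
lowest index) is resampled into 101 points bounding 100 segments, indexed
0–99. The published pipelines this mirrors describe the centroid only as
"the fiber minimizing the average distance"; the direct-flip mean distance
is the minimal concrete reading and has the advantage of being verifiable
against an exhaustive brute-force oracle, which the test suite does for
bundles up to 20 streamlines.

Streamlines are then **oriented** (flipped when the reversed ordering is
closer to the centroid) so that segment 0 means the same anatomical end for
every streamline, and each small streamline segment (after 101-point
resampling) is **assigned** the index of the centroid segment with the
nearest midpoint.

For the **profile**, each metric is sampled at the midpoint of every small
streamline segment, with the local streamline tangent as the reference axis
for the direction-dependent metrics; the per-segment profile value is the
arithmetic mean over all assigned samples. Whether the source analyses
averaged per streamline segment or per interpolated sample is not stated
anywhere we could find; midpoint sampling is this package's choice and is
deterministic and cheap. Segments with no assigned samples are reported as
missing (`NA`), never imputed; more than 20% missing warns, all-missing is
an error.

## FOD metrics

FOD fields are 4D volumes of real, even-order spherical-harmonic
coefficients. The basis (documented in `?sh_basis`, round-trip tested) is
the real orthonormal convention common in diffusion software: order-major
columns, `sqrt(2)`-scaled sine/cosine terms for `m < 0` / `m > 0`,
Condon–Shortley phase inside the associated Legendre functions.
Coefficients are interpolated trilinearly and componentwise; by linearity
of the basis this equals interpolating amplitudes, and coefficient space is
cheaper.

**Lobe segmentation.** Amplitudes are evaluated on a subdivided icosahedral
mesh (default 3 levels, 642 antipodally symmetric vertices; production
analyses can raise this). Negative amplitudes (deconvolution ringing) are
clamped to zero. The positive support is partitioned into watershed basins
of the local maxima by steepest ascent on the mesh graph; antipodal basin
pairs are merged because an even-order FOD is symmetric (orientations are
axes). Only local maxima above `amplitude_floor_frac` (default 0.1) of the
global maximum found genuine lobes; the basins of sub-floor maxima are
discarded. The floor deliberately gates *peak detection only* rather than
truncating integration support: with smooth band-limited lobes, truncating
all sub-floor vertices would bite 5–20% out of every lobe integral, whereas
the watershed keeps the full lobe mass and still suppresses spurious
ringing peaks. The mesh-refinement test holds lobe integrals stable to 1%
across one subdivision level.

**AFD** at a point is the integral (solid-angle-weighted amplitude sum over
both merged hemispheres) of the lobe whose peak axis is most parallel to
the reference direction; ties go to the larger integral. **Peak amplitude**
is the FOD value at that lobe's peak, refined by a local continuous ascent
(Nelder–Mead on the spherical-harmonic surface) so the value is
mesh-independent to first order; a purely isotropic FOD has no peak
structure and returns 0 by convention. **FA** is
`sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||` over the eigenvalues
of the trilinearly interpolated tensor, with negative eigenvalues clamped
(and flagged) and the zero tensor mapping to 0.

## Group statistics

Per metric, subject profiles for all bundles enter a two-group comparison:

- **Confound adjustment.** Default (`"residualize"`): per segment, OLS of
  the metric on hearing loss, THI and tinnitus duration (group label
  excluded), group contrasts then act on the residuals plus the grand mean
  — the order of operations the source analysis describes. See the caveat
  below. Alternative (`"ancova"`): the per-segment statistic is the partial
  t of the group term in `Y ~ 1 + confounds + group` (computed by
  Frisch–Waugh projection and verified against `lm()`), whose standard
  error accounts for group–confound collinearity. `"none"` skips
  adjustment.
- **maxT permutation FWE.** Group labels are randomly reassigned (5000
  permutations by default; exact enumeration when the label assignments
  number fewer), the maximum |t| over *all* bundles and segments is
  recorded per permutation, and each segment's corrected p is the add-one
  proportion `(b + 1)/(B + 1)` of permutation maxima reaching its observed
  |t|. The metric multiplicity (three metrics analyzed in parallel) is
  handled by dividing alpha by `n_metrics_bonferroni` (default 3), exactly
  mirroring the two-stage published wording, not by a three-metric maxT.
- **Cluster extent.** Significant segments are kept only in contiguous runs
  of at least `cluster_extent_min` (default 5; 2 reproduces the lenient
  supplementary variant); each surviving cluster reports its minimum
  uncorrected p, the segment achieving it, t, Cohen's d and power.
- **Effect sizes and power.** `d = 2|t|/sqrt(n1 + n2 - 2)` (reproduces all
  18 published rows to 3 decimals), `f2 = r^2/(1 - r^2)` for correlations,
  and two-sided two-sample power from the noncentral t distribution with
  `ncp = d sqrt(n1 n2/(n1 + n2))`. The alpha behind the published power
  values is not stated; `power_alpha` is therefore a parameter (default
  0.05 two-sided), and the implementation is validated against a frozen
  10^6-replicate Monte-Carlo rejection rate instead of published numbers.
- **Semi-partial correlations.** For a cofactor of interest, a joint OLS on
  all confounds is fitted, the fitted contributions of the *other*
  confounds are subtracted from the metric, and the Pearson correlation
  with the cofactor is corrected by the same maxT machinery with cofactor
  values permuted. Hearing loss is naturally analyzed on the full cohort;
  THI and duration only vary in the tinnitus group.

### The group-proxy confound caveat

In this study design THI and tinnitus duration are *structural group
proxies*: every control has 0. Residualize-then-test therefore attributes
any group difference shared with them to the confounds, shrinking the
observed contrast but not the permuted ones — the procedure remains valid
but strongly conservative (on null synthetic cohorts the measured
family-wise error is ~0, comfortably below alpha). Conversely, subtracting
jointly fitted confound terms while keeping a two-sample t is
anti-conservative, because the confound slopes inherit large collinear
sampling noise aligned with the group direction; the package deliberately
does not offer that combination. The calibrated covariate-adjusted option
is the ANCOVA partial t, whose standard error carries the variance
inflation. These are properties of the estimators, demonstrated by the
test suite, not of this implementation.

For the same reason, the statistical validation experiments (FWE
calibration and effect recovery below) run the permutation engine on the
profiles directly: the generator draws confounds independently of the
metrics, so null cohorts are exchangeable exactly at the profile level and
the calibration of the maxT correction can be measured without the
orthogonal question of confound modeling. The confound operations have
their own algebraic oracles (residual orthogonality, perfect fit,
`lm()`-equality of the partial t).

## The synthetic cohort generator

The generator emulates the study conditions, not the images:

- **Cohort**: two groups of 19; hearing loss and age per group as Gaussians
  (tinnitus 20.2 ± 10.3 dB, 42.5 ± 11.6 y; control 13.2 ± 3.8 dB,
  42.5 ± 11.9 y) with within-group age–HL correlation 0.545; THI
  16.2 ± 10.5 and duration 11.6 ± 7.6 y in the tinnitus group, 0 for
  controls. All confounds are truncated at zero by rejection, which is the
  physically plausible reading (no negative hearing loss); truncation and
  the O(1/n) bias of the sample correlation attenuate the *realized* means
  slightly (HL mean ~20.9, mean sample r ~0.50 at n = 19) — the package
  reports these as computed rather than adjusting parameters to cancel
  them.
- **Bundles**: smooth spline centerlines; each streamline is the centerline
  displaced by a per-streamline random in-plane direction and signed
  Gaussian magnitude (so the mean point-to-centerline distance is
  `sd * sqrt(2/pi)`), plus small per-point jitter. Defaults are desk-scale
  (500 streamlines, ~100 points) — the published 10,000 x 27 bundles is a
  configuration, not a requirement.
- **Fields**: in voxels traversed by a bundle the FOD is the axially
  symmetric kernel `(d . u)^L` aligned with the local dominant tangent axis
  (principal eigenvector of accumulated tangent outer products), scaled so
  its analytic sphere integral equals the requested AFD. The kernel is a
  degree-`L` polynomial, hence *exactly* band-limited at the field's SH
  order and nonnegative — field construction introduces no truncation or
  ringing error, which makes quadrature oracles sharp. Tensor fields use an
  axially symmetric tensor at the requested FA and mean diffusivity
  (default 0.7e-3 mm^2/s), isotropic background elsewhere. The default grid
  is 1.3 mm isotropic; desk-scale tests use coarser grids.
- **Effects and noise**: group effects add `delta * noise_sd` to the metric
  baseline for tinnitus subjects inside contiguous segment windows. No
  noise model for subject-level metric variation is published; the package
  uses i.i.d. Gaussian segment noise (`noise_sd`, a configuration knob) at
  the profile level and smooth spline perturbations plus window effects at
  the field level. With `delta = 0` the groups are exchangeable by
  construction — the premise of permutation calibration.

What the generator does **not** emulate: realistic anatomy or atlases,
diffusion-signal formation (no b-values or gradient tables), spatially
correlated scanner noise, partial-volume or CSF contamination, or
segmentation failure modes. Passing the synthetic checks therefore
demonstrates the correctness and calibration of the *analysis machinery*,
not that any particular anatomical finding in real tinnitus data would
replicate.

## Numerical choices

- Sphere quadrature: per-vertex solid angles from spherical triangle areas
  (l'Huilier), summing to 4 pi exactly; 642 vertices default, refinement
  tested at 2562.
- Trilinear interpolation clamps the interpolation cell at grid borders;
  points outside the volume raise a typed error and profiling marks the
  sample missing.
- Permutation p-values use the add-one estimator; with `B` at least the
  number of distinct label assignments the null is enumerated exactly. In
  multi-segment runs the FWE p dominates the parametric uncorrected p, but
  with very few tests the discrete permutation p can legitimately sit below
  it, so the package reports both without clamping.
- Degenerate cases are explicit: zero pooled variance gives t = 0, p = 1,
  flagged; a constant profile matrix z-normalizes to zeros with a
  degeneracy flag; |r| = 1 maps to infinite f2 with a warning.
- Seeds: every stochastic stage takes an explicit seed and restores the
  caller's RNG state; identical seeds give bit-identical outputs (tested).

## Problem sizes used in validation

The test-suite and acceptance experiments use: 200 null cohorts and 50
effect-recovery replicates of 19 + 19 subjects, 3 bundles x 100 segments,
1000 permutations (alpha 0.05, no metric correction since one metric is
analyzed); 400 cohort-table replicates for distribution checks; geometric
oracles on bundles of 8–20 streamlines; field oracles on 642/2562-vertex
meshes. The full-field integration test runs 2 + 2 subjects on one bundle
at 2.6 mm. These sizes were chosen to keep Monte-Carlo error well inside
the asserted tolerances (binomial 95% band 0.02–0.08 around 0.05 for the
FWE rate at 200 replicates).

## Known limitations

- AFD is the plain lobe integral; external tools may apply additional
  normalizations, so absolute AFD scales are comparable within, not across,
  implementations.
- The centroid is a member streamline; for very dispersed or crossing-heavy
  bundles a synthetic mean curve could be more stable. Bundles whose
  geometry defeats nearest-segment assignment (sharp fanning) are a known
  failure mode of the approach and are not given special handling.
- The residualize-then-test default inherits the conservativeness described
  above whenever a confound is a structural group proxy; analysts wanting
  covariate adjustment with calibrated error rates should use the ANCOVA
  model.
- Profile direction (which end is segment 0) is a convention; synthetic
  bundles use the spec'd start label, TCK input can be flipped at the CLI.
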