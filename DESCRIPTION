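Package: tractoprofile
Title: Along-Tract Profiling and Permutation Statistics for White-Matter Bundles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tractometry analysis of white-matter fiber bundles: computes
    100-segment along-tract profiles of apparent fiber density (AFD, the
    integral of the fiber orientation distribution lobe), FOD peak amplitude
    and tensor-derived fractional anisotropy from streamline bundles and
    voxelwise spherical-harmonic or tensor fields; compares two groups per
    bundle and per segment with confound regression, maxT permutation-based
    family-wise error control and cluster-extent filtering; reports Cohen's d,
    Cohen's f2, post-hoc power and semi-partial cofactor correlations. A
    synthetic-cohort generator produces bundle geometries, FOD/tensor volumes
    and two-group cohort tables with injected localized effects so the whole
    pipeline is testable without MRI data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    yaml,
    ggplot2,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
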