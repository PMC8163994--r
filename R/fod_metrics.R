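#' Evaluate an FOD field at a world-space point
#'
#' Trilinearly interpolates the spherical-harmonic coefficients at
#' `point_mm` (componentwise; by linearity of the basis this equals
#' interpolating amplitudes) and synthesizes amplitudes along the requested
#' directions.
#'
#' @param field A [fod_field()].
#' @param point_mm Length-3 world coordinate (mm).
#' @param directions n x 3 unit vectors.
#' @param clamp If `TRUE` (default), negative amplitudes (deconvolution
#'   ringing) are clamped to 0, the convention used for integration; set
#'   `FALSE` for the raw synthesis.
#' @return Numeric amplitude vector of length n.
#' @export
evaluate_fod <- function(field, point_mm, directions, clamp = TRUE) {
  stopifnot(inherits(field, "fod_field"))
  coef <- drop(interp_field(field$coefficients, field$affine,
                            matrix(point_mm, 1)))
  amp <- drop(sh_basis(directions, field$sh_order) %*% coef)
  if (clamp) amp <- pmax(amp, 0)
  amp
}

# Interpolated coefficient vectors for many points at once (n x n_sh).
fod_coefficients_at <- function(field, points_mm) {
  interp_field(field$coefficients, field$affine, points_mm)
}

# Steepest-ascent basin labels on the mesh graph for one amplitude vector.
# Every positive-amplitude vertex points to its largest-amplitude neighbor
# (itself when it is a local maximum); pointer-jumping converges to the
# basin root, partitioning the FOD's support into watershed basins of its
# local maxima. Zero-amplitude vertices get label 0.
mesh_basins <- function(amplitudes, mesh) {
  n <- length(amplitudes)
  active <- amplitudes > 0
  ptr <- seq_len(n)
  for (i in which(active)) {
    nb <- mesh$adjacency[[i]]
    nb <- nb[active[nb]]
    cand <- c(i, nb)
    ptr[i] <- cand[which.max(amplitudes[cand])]
  }
  # pointer jumping to the root
  repeat {
    nxt <- ptr[ptr]
    if (all(nxt == ptr)) break
    ptr <- nxt
  }
  ptr[!active] <- 0L
  ptr
}

#' Segment an FOD into lobes at a point
#'
#' Partitions the positive part of the FOD amplitude sphere into watershed
#' basins of its local maxima by steepest ascent on the mesh graph, then
#' merges the two antipodal halves of each lobe (an even-order FOD is
#' antipodally symmetric, so orientations are axes). Only maxima above
#' `amplitude_floor_frac` times the global maximum count as genuine lobes —
#' the floor suppresses spurious peaks from deconvolution ringing without
#' truncating real lobe mass; basins of sub-floor maxima are discarded.
#' Each surviving lobe's integral is the solid-angle-weighted sum of its
#' (clamped) amplitudes over both halves — the quantity whose
#' bundle-aligned value is the apparent fiber density.
#'
#' @param field A [fod_field()].
#' @param point_mm Length-3 world coordinate (mm).
#' @param mesh A [sphere_mesh()].
#' @param amplitude_floor_frac Local maxima below this fraction of the
#'   global maximum do not form lobes (default 0.1).
#' @return List of lobes sorted by integral, descending; each a list with
#'   `peak_direction` (unit axis, z >= 0 hemisphere), `peak_amplitude`
#'   (mesh-vertex value; see [peak_amplitude_along()] for the refined one),
#'   `integral`, and `vertex_set` (indices into `mesh$vertices`, both
#'   hemispheres). Empty list when the FOD is all-zero (or entirely
#'   sub-floor).
#' @export
segment_lobes <- function(field, point_mm, mesh = sphere_mesh(3L),
                          amplitude_floor_frac = 0.1) {
  stopifnot(amplitude_floor_frac >= 0, amplitude_floor_frac < 1)
  amp <- evaluate_fod(field, point_mm, mesh$vertices, clamp = TRUE)
  lobes_from_amplitudes(amp, mesh, amplitude_floor_frac)
}

# Core lobe segmentation given precomputed clamped amplitudes at mesh vertices.
lobes_from_amplitudes <- function(amp, mesh, amplitude_floor_frac) {
  mx <- max(amp)
  if (mx <= 0) return(list())
  labels <- mesh_basins(amp, mesh)
  roots <- setdiff(unique(labels), 0L)
  roots <- roots[amp[roots] > amplitude_floor_frac * mx]
  labels[!(labels %in% roots)] <- 0L
  if (length(roots) == 0) return(list())
  # merge antipodal root pairs
  root_of <- integer(length(labels))
  root_of[roots] <- roots
  merged <- list()
  seen <- integer(0)
  for (r in roots) {
    if (r %in% seen) next
    anti_vertex <- mesh$antipode[r]
    anti_root <- labels[anti_vertex]
    partner <- if (anti_root %in% roots && !(anti_root %in% seen) &&
                   anti_root != r) anti_root else NA_integer_
    members <- which(labels == r)
    if (!is.na(partner)) {
      members <- c(members, which(labels == partner))
      seen <- c(seen, r, partner)
    } else {
      seen <- c(seen, r)
    }
    peak_idx <- members[which.max(amp[members])]
    pk <- mesh$vertices[peak_idx, ]
    if (pk[3] < 0 || (pk[3] == 0 && (pk[1] < 0 || (pk[1] == 0 && pk[2] < 0))))
      pk <- -pk
    merged[[length(merged) + 1L]] <- list(
      peak_direction = pk,
      peak_amplitude = amp[peak_idx],
      integral = sum(amp[members] * mesh$solid_angles[members]),
      vertex_set = sort(members))
  }
  merged[order(vapply(merged, `[[`, numeric(1), "integral"),
               decreasing = TRUE)]
}

# Select the lobe whose axis is most parallel to the reference direction;
# ties (equal |dot|) go to the larger integral, which is first in the
# integral-sorted list.
select_lobe <- function(lobes, reference_dir) {
  if (length(lobes) == 0) return(NULL)
  dots <- vapply(lobes, function(l) abs(sum(l$peak_direction * reference_dir)),
                 numeric(1))
  lobes[[which.max(dots)]]
}

#' Apparent fiber density along a reference direction
#'
#' AFD at a point: the integral of the FOD lobe whose peak axis is most
#' parallel (largest absolute dot product) to `reference_dir` — in
#' tractometry, the local streamline tangent. Returns 0 when no lobe exists.
#'
#' @inheritParams segment_lobes
#' @param reference_dir Length-3 unit vector (treated as an axis).
#' @return Nonnegative scalar.
#' @export
afd_along <- function(field, point_mm, reference_dir, mesh = sphere_mesh(3L),
                      amplitude_floor_frac = 0.1) {
  lobe <- select_lobe(segment_lobes(field, point_mm, mesh,
                                    amplitude_floor_frac), reference_dir)
  if (is.null(lobe)) 0 else lobe$integral
}

#' FOD peak amplitude along a reference direction
#'
#' Selects the lobe as in [afd_along()] and returns the FOD amplitude at its
#' peak, refined by a local continuous ascent on the spherical-harmonic
#' surface starting from the peak mesh vertex (Nelder-Mead in spherical
#' coordinates), so the value does not depend on the mesh resolution to
#' first order. Returns 0 when no lobe exists — in particular for a purely
#' isotropic FOD, which has no supra-floor local-maximum structure once the
#' floor is applied to a constant amplitude sphere (every vertex ties; the
#' convention here is that an FOD whose anisotropic part is zero carries no
#' directional fiber population, so the peak amplitude is reported as the
#' isotropic amplitude only when a genuine basin exists).
#'
#' @inheritParams afd_along
#' @return Nonnegative scalar.
#' @export
peak_amplitude_along <- function(field, point_mm, reference_dir,
                                 mesh = sphere_mesh(3L),
                                 amplitude_floor_frac = 0.1) {
  amp <- evaluate_fod(field, point_mm, mesh$vertices, clamp = TRUE)
  mx <- max(amp)
  if (mx <= 0) return(0)
  if (diff(range(amp)) <= 1e-9 * mx) return(0)  # isotropic: no peak structure
  lobes <- lobes_from_amplitudes(amp, mesh, amplitude_floor_frac)
  lobe <- select_lobe(lobes, reference_dir)
  if (is.null(lobe)) return(0)
  coef <- drop(interp_field(field$coefficients, field$affine,
                            matrix(point_mm, 1)))
  neg_amp <- function(tp) {
    d <- c(sin(tp[1]) * cos(tp[2]), sin(tp[1]) * sin(tp[2]), cos(tp[1]))
    -max(0, sum(sh_basis(matrix(d, 1), field$sh_order) * coef))
  }
  v <- lobe$peak_direction
  start <- c(acos(pmin(1, pmax(-1, v[3]))), atan2(v[2], v[1]))
  opt <- stats::optim(start, neg_amp, method = "Nelder-Mead",
                      control = list(maxit = 60, reltol = 1e-10))
  max(lobe$peak_amplitude, -opt$value)
}

#' Fractional anisotropy of a tensor field at a point
#'
#' Trilinearly interpolates the six tensor components, eigen-decomposes, and
#' evaluates `FA = sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||`.
#' Negative eigenvalues arising from interpolation or noise are clamped to 0
#' (with a warning); a zero tensor gives FA = 0 by convention.
#'
#' @param field A [tensor_field()].
#' @param point_mm Length-3 world coordinate (mm).
#' @return Scalar in [0, 1].
#' @export
fa_at <- function(field, point_mm) {
  stopifnot(inherits(field, "tensor_field"))
  comp <- drop(interp_field(field$tensors, field$affine, matrix(point_mm, 1)))
  fa_from_components(comp)
}

fa_from_components <- function(comp) {
  D <- matrix(c(comp[1], comp[2], comp[3],
                comp[2], comp[4], comp[5],
                comp[3], comp[5], comp[6]), 3, 3)
  ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-10 * max(abs(ev), 1e-300)))
    warning("negative tensor eigenvalue clamped to 0")
  ev <- pmax(ev, 0)
  nrm <- sqrt(sum(ev^2))
  if (nrm == 0) return(0)
  sqrt(3 / 2) * sqrt(sum((ev - mean(ev))^2)) / nrm
}
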