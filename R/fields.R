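#' Construct an FOD coefficient field
#'
#' A fiber orientation distribution field: a 4D array of even-order real
#' spherical-harmonic coefficients (see [sh_basis()] for the basis
#' convention) on a voxel grid with a voxel-to-world affine. Voxel indices
#' are 0-based in the affine convention (world = A %*% c(i, j, k, 1)),
#' coordinates are world-space millimetres, RAS+.
#'
#' @param coefficients 4D numeric array (nx, ny, nz, n_sh).
#' @param affine 4 x 4 voxel-to-world matrix (invertible).
#' @param sh_order Even spherical-harmonic order; inferred from the 4th
#'   dimension when omitted.
#' @return Object of class `fod_field`.
#' @export
fod_field <- function(coefficients, affine, sh_order = NULL) {
  stopifnot(length(dim(coefficients)) == 4, all(dim(affine) == c(4, 4)))
  if (abs(det(affine)) < 1e-12) stop("affine is not invertible")
  n_sh <- dim(coefficients)[4]
  if (is.null(sh_order)) sh_order <- sh_order_from_n(n_sh)
  if (sh_n_coef(sh_order) != n_sh)
    stop("4th dimension (", n_sh, ") does not match sh_order ", sh_order)
  structure(list(coefficients = coefficients, affine = affine,
                 sh_order = as.integer(sh_order)),
            class = "fod_field")
}

#' Construct a diffusion-tensor field
#'
#' @param tensors 4D numeric array (nx, ny, nz, 6); component order along the
#'   4th dimension is (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz).
#' @param affine 4 x 4 voxel-to-world matrix.
#' @return Object of class `tensor_field`.
#' @export
tensor_field <- function(tensors, affine) {
  stopifnot(length(dim(tensors)) == 4, dim(tensors)[4] == 6,
            all(dim(affine) == c(4, 4)))
  if (abs(det(affine)) < 1e-12) stop("affine is not invertible")
  structure(list(tensors = tensors, affine = affine), class = "tensor_field")
}

#' Voxel grid covering a set of world-space points
#'
#' Convenience for the synthetic generators: an axis-aligned grid with
#' isotropic voxels enclosing `points` plus a margin.
#'
#' @param points n x 3 world coordinates (mm).
#' @param voxel_size_mm Isotropic voxel edge (default 1.3 mm).
#' @param margin_mm Padding added on every side.
#' @return List with `dim` (3 integers) and `affine` (4 x 4).
#' @export
make_grid <- function(points, voxel_size_mm = 1.3, margin_mm = 4) {
  points <- rbind(points)
  lo <- apply(points, 2, min) - margin_mm
  hi <- apply(points, 2, max) + margin_mm
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / voxel_size_mm)) + 1L)
  affine <- diag(c(rep(voxel_size_mm, 3), 1))
  affine[1:3, 4] <- lo
  list(dim = dims, affine = affine)
}

world_to_voxel <- function(affine, points_mm) {
  points_mm <- rbind(points_mm)
  inv <- solve(affine)
  t(inv[1:3, 1:3] %*% t(points_mm) + inv[1:3, 4])
}

voxel_to_world <- function(affine, ijk) {
  ijk <- rbind(ijk)
  t(affine[1:3, 1:3] %*% t(ijk) + affine[1:3, 4])
}

# Trilinear interpolation of a 4D component array at world points.
# Returns an n x ncomp matrix. Points outside the grid raise an error
# (callers that can skip catch it).
interp_field <- function(arr, affine, points_mm) {
  points_mm <- rbind(points_mm)
  d <- dim(arr)
  vox <- world_to_voxel(affine, points_mm)
  if (any(vox < -0.5) ||
      any(sweep(vox, 2, d[1:3] - 0.5, ">")))
    stop("point outside field bounding box")
  # clamp the interpolation cell to the grid so border points use edge values
  f0 <- pmin(pmax(floor(vox), 0), matrix(d[1:3] - 1, nrow(vox), 3, byrow = TRUE))
  f1 <- pmin(f0 + 1, matrix(d[1:3] - 1, nrow(vox), 3, byrow = TRUE))
  w <- pmin(pmax(vox - f0, 0), 1)
  n <- nrow(vox); ncomp <- d[4]
  out <- matrix(0, n, ncomp)
  comp_stride <- d[1] * d[2] * d[3]
  base_comp <- (seq_len(ncomp) - 1L) * comp_stride
  for (corner in 0:7) {
    cx <- bitwAnd(corner, 1L); cy <- bitwAnd(bitwShiftR(corner, 1L), 1L)
    cz <- bitwAnd(bitwShiftR(corner, 2L), 1L)
    ix <- if (cx) f1[, 1] else f0[, 1]
    iy <- if (cy) f1[, 2] else f0[, 2]
    iz <- if (cz) f1[, 3] else f0[, 3]
    wt <- (if (cx) w[, 1] else 1 - w[, 1]) *
          (if (cy) w[, 2] else 1 - w[, 2]) *
          (if (cz) w[, 3] else 1 - w[, 3])
    lin <- 1L + ix + d[1] * (iy + d[2] * iz)
    out <- out + wt * arr[outer(lin, base_comp, "+")]
  }
  out
}

# Per-voxel linear index helpers used by the synthetic field builders
voxel_linear_index <- function(dims, ijk) {
  1L + ijk[, 1] + dims[1] * (ijk[, 2] + dims[2] * ijk[, 3])
}
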