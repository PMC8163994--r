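# Shared fixtures: built in code, small enough for fast tests.

# A straight bundle along +x of given dispersion.
straight_bundle <- function(n_streamlines = 30, dispersion = 1, length_mm = 50,
                            points = 40, seed = 3) {
  make_bundle(bundle_spec("straight",
                          rbind(c(0, 0, 0), c(length_mm, 0, 0)),
                          n_streamlines = n_streamlines,
                          radial_dispersion_mm = dispersion,
                          points_per_streamline = points, seed = seed))
}

# An FOD field whose EVERY voxel holds the x-aligned lobe kernel scaled to
# AFD = afd_fun(world x); no occupancy boundary, so along-tract profiling
# can be checked against the analytic field with only interpolation error.
filled_fod_field <- function(afd_fun, sh_order = 8L,
                             dims = c(30, 7, 7), voxel = 2,
                             origin = c(-4, -6, -6),
                             mesh = sphere_mesh(2L)) {
  affine <- diag(c(voxel, voxel, voxel, 1))
  affine[1:3, 4] <- origin
  ker <- sh_lobe_kernel(c(1, 0, 0), sh_order, integral = 1, mesh = mesh)
  n_sh <- sh_n_coef(sh_order)
  coefs <- array(0, c(dims, n_sh))
  xs <- origin[1] + voxel * (seq_len(dims[1]) - 1)
  for (i in seq_len(dims[1])) {
    for (j in seq_len(n_sh)) coefs[i, , , j] <- ker[j] * afd_fun(xs[i])
  }
  fod_field(coefs, affine, sh_order)
}

# Single-voxel-style field: a small grid with identical coefficients
# everywhere, so interpolation returns the coefficients exactly.
uniform_fod_field <- function(coefficients, voxel = 2, dims = c(3, 3, 3)) {
  affine <- diag(c(voxel, voxel, voxel, 1))
  affine[1:3, 4] <- -voxel
  arr <- array(rep(coefficients, each = prod(dims)),
               c(dims, length(coefficients)))
  fod_field(arr, affine)
}

uniform_tensor_field <- function(comp, voxel = 2, dims = c(3, 3, 3)) {
  affine <- diag(c(voxel, voxel, voxel, 1))
  affine[1:3, 4] <- -voxel
  tensor_field(array(rep(comp, each = prod(dims)), c(dims, 6)), affine)
}

# Brute-force direct-flip mean distance between equal-length polylines.
bf_mdf <- function(a, b) {
  n <- nrow(a)
  min(mean(sqrt(rowSums((a - b)^2))),
      mean(sqrt(rowSums((a - b[n:1, ])^2))))
}

# Random wiggly streamline roughly along +x.
random_streamline <- function(n_pts = 12, seed_offset = 0) {
  cbind(sort(stats::runif(n_pts, 0, 50)),
        cumsum(stats::rnorm(n_pts)), cumsum(stats::rnorm(n_pts)))
}
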