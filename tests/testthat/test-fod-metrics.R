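test_that("FOD evaluation: isotropy, antipodal symmetry, Legendre oracle", {
  # order-0-only field is isotropic with amplitude c0 / (2 sqrt(pi))
  c0 <- 3.2
  f <- uniform_fod_field(c(c0, rep(0, 14)))
  dirs <- rbind(c(1, 0, 0), c(0, 0, 1), c(1, 1, 1) / sqrt(3))
  expect_equal(evaluate_fod(f, c(0, 0, 0), dirs),
               rep(c0 / (2 * sqrt(pi)), 3), tolerance = 1e-12)

  # even-order field: f(d) == f(-d)
  set.seed(21)
  coef <- rnorm(sh_n_coef(8))
  f <- uniform_fod_field(coef)
  u <- matrix(rnorm(60), ncol = 3); u <- u / sqrt(rowSums(u^2))
  expect_equal(evaluate_fod(f, c(0, 0, 0), u, clamp = FALSE),
               evaluate_fod(f, c(0, 0, 0), -u, clamp = FALSE),
               tolerance = 1e-10)

  # raw synthesis equals the independent basis oracle
  B <- sh_basis(u, 8L)
  expect_equal(evaluate_fod(f, c(0, 0, 0), u, clamp = FALSE),
               drop(B %*% coef), tolerance = 1e-10)
})

test_that("lobe segmentation: single population, crossing, refinement", {
  mesh <- sphere_mesh(3L)
  # single axially symmetric population: one merged lobe, full integral
  ker <- sh_lobe_kernel(c(1, 1, 0) / sqrt(2), 8L, integral = 1.0, mesh = mesh)
  f <- uniform_fod_field(ker)
  lobes <- segment_lobes(f, c(0, 0, 0), mesh)
  expect_length(lobes, 1)
  expect_equal(lobes[[1]]$integral, 1.0, tolerance = 5e-3)

  # all-zero FOD: empty list
  expect_length(segment_lobes(uniform_fod_field(rep(0, 45)), c(0, 0, 0), mesh),
                0)

  # 90-degree crossing at 0.6 / 0.4: two lobes, ratio 1.5
  ker2 <- 0.6 * sh_lobe_kernel(c(1, 0, 0), 8L, mesh = mesh) +
          0.4 * sh_lobe_kernel(c(0, 0, 1), 8L, mesh = mesh)
  f2 <- uniform_fod_field(ker2)
  lobes2 <- segment_lobes(f2, c(0, 0, 0), mesh)
  expect_length(lobes2, 2)
  expect_equal(lobes2[[1]]$integral, 0.6, tolerance = 0.02)
  expect_equal(lobes2[[2]]$integral, 0.4, tolerance = 0.02)
  expect_equal(lobes2[[1]]$integral / lobes2[[2]]$integral, 1.5,
               tolerance = 0.05)

  # refinement oracle: one finer subdivision changes integrals <= 1%
  lobes_f <- segment_lobes(f2, c(0, 0, 0), sphere_mesh(4L))
  for (k in 1:2)
    expect_lt(abs(lobes2[[k]]$integral - lobes_f[[k]]$integral) /
                lobes_f[[k]]$integral, 0.01)

  # quadrature consistency: lobes never exceed the whole-sphere integral
  amp <- evaluate_fod(f2, c(0, 0, 0), mesh$vertices)
  whole <- sum(amp * mesh$solid_angles)
  expect_lte(sum(vapply(lobes2, `[[`, numeric(1), "integral")),
             whole + 1e-9)
})

test_that("AFD selects the lobe most parallel to the reference axis", {
  mesh <- sphere_mesh(3L)
  ker <- sh_lobe_kernel(c(0, 0, 1), 8L, integral = 0.9, mesh = mesh)
  f <- uniform_fod_field(ker)
  # reference along the lobe axis
  expect_equal(afd_along(f, c(0, 0, 0), c(0, 0, 1), mesh), 0.9,
               tolerance = 5e-3)
  # a single lobe is selected even for a perpendicular reference
  expect_equal(afd_along(f, c(0, 0, 0), c(1, 0, 0), mesh), 0.9,
               tolerance = 5e-3)
  # crossing: the minor population is returned for its own axis
  ker2 <- 0.6 * sh_lobe_kernel(c(1, 0, 0), 8L, mesh = mesh) +
          0.4 * sh_lobe_kernel(c(0, 0, 1), 8L, mesh = mesh)
  f2 <- uniform_fod_field(ker2)
  expect_equal(afd_along(f2, c(0, 0, 0), c(0, 0, 1), mesh), 0.4,
               tolerance = 0.02)
  expect_equal(afd_along(f2, c(0, 0, 0), c(1, 0, 0), mesh), 0.6,
               tolerance = 0.02)
})

test_that("peak amplitude: analytic kernel maximum, linearity, conventions", {
  mesh <- sphere_mesh(3L)
  ker <- sh_lobe_kernel(c(0, 1, 1) / sqrt(2), 8L, integral = 1, mesh = mesh)
  f <- uniform_fod_field(ker)
  analytic_max <- 9 / (4 * pi)  # amplitude scale of the degree-8 kernel
  pk <- peak_amplitude_along(f, c(0, 0, 0), c(0, 1, 1) / sqrt(2), mesh)
  expect_equal(pk, analytic_max, tolerance = 0.01)

  # doubling the coefficients doubles the peak
  f2 <- uniform_fod_field(2 * ker)
  expect_equal(peak_amplitude_along(f2, c(0, 0, 0), c(0, 1, 1) / sqrt(2),
                                    mesh),
               2 * pk, tolerance = 1e-6)

  # isotropic-only FOD: no peak structure, 0 by convention
  expect_equal(peak_amplitude_along(uniform_fod_field(c(1, rep(0, 14))),
                                    c(0, 0, 0), c(0, 0, 1), mesh), 0)
})

test_that("rotation equivariance of AFD and peak amplitude", {
  mesh <- sphere_mesh(3L)
  ker <- 0.7 * sh_lobe_kernel(c(1, 0, 0), 8L, mesh = mesh) +
         0.3 * sh_lobe_kernel(c(0, 1, 1) / sqrt(2), 8L, mesh = mesh)
  f <- uniform_fod_field(ker)
  # a rotation by 35 degrees about an oblique axis, coefficients rotated by
  # re-projection of the rotated band-limited function (exact)
  ax <- c(1, 2, 0.5); ax <- ax / sqrt(sum(ax^2))
  th <- 35 * pi / 180
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  # evaluating at R^T-rotated directions yields g(v) = f(R^T v): the lobe
  # originally along u moves to R u, so the reference rotates by R too
  vals_rot <- drop(sh_basis(mesh$vertices %*% R, 8L) %*% ker)
  ker_rot <- sh_project(mesh$vertices, vals_rot, 8L)
  f_rot <- uniform_fod_field(ker_rot)
  ref <- c(1, 0, 0)
  ref_rot <- drop(R %*% ref)
  expect_equal(afd_along(f_rot, c(0, 0, 0), ref_rot, mesh),
               afd_along(f, c(0, 0, 0), ref, mesh), tolerance = 0.01)
  expect_equal(peak_amplitude_along(f_rot, c(0, 0, 0), ref_rot, mesh),
               peak_amplitude_along(f, c(0, 0, 0), ref, mesh),
               tolerance = 0.01)
})

test_that("FA: closed-form eigenvalue oracle and invariances", {
  # isotropic -> 0; rank-1 -> 1
  expect_equal(fa_at(uniform_tensor_field(c(2, 0, 0, 2, 0, 2) * 1e-3),
                     c(0, 0, 0)), 0, tolerance = 1e-12)
  expect_equal(fa_at(uniform_tensor_field(c(1.4e-3, 0, 0, 0, 0, 0)),
                     c(0, 0, 0)), 1, tolerance = 1e-12)

  # oracle: independent eigen + formula for lambda = (1.7, .3, .3) 1e-3,
  # randomly rotated so off-diagonals are exercised
  set.seed(31)
  lam <- c(1.7, 0.3, 0.3) * 1e-3
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  D <- Q %*% diag(lam) %*% t(Q)
  comp <- D[c(1, 2, 3, 5, 6, 9)]
  ev <- eigen(matrix(c(comp[1], comp[2], comp[3], comp[2], comp[4], comp[5],
                       comp[3], comp[5], comp[6]), 3, 3),
              symmetric = TRUE, only.values = TRUE)$values
  oracle <- sqrt(3 / 2) * sqrt(sum((ev - mean(ev))^2)) / sqrt(sum(ev^2))
  expect_equal(fa_at(uniform_tensor_field(comp), c(0, 0, 0)), oracle,
               tolerance = 1e-12)

  # scale invariance and bounds
  expect_equal(fa_at(uniform_tensor_field(comp * 1e4), c(0, 0, 0)), oracle,
               tolerance = 1e-12)
  expect_equal(fa_at(uniform_tensor_field(rep(0, 6)), c(0, 0, 0)), 0)
  set.seed(32)
  for (i in 1:20) {
    A <- matrix(rnorm(9), 3); S <- crossprod(A)
    v <- fa_at(uniform_tensor_field(S[c(1, 2, 3, 5, 6, 9)]), c(0, 0, 0))
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("points outside the field raise an out-of-bounds error", {
  f <- uniform_fod_field(c(1, rep(0, 14)))
  expect_error(evaluate_fod(f, c(1e3, 0, 0), rbind(c(0, 0, 1))),
               "outside")
})
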