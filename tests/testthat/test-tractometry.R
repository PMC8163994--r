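test_that("arc-length resampling: equal spacing, identity, helix length", {
  seg <- rbind(c(0, 0, 0), c(9, 0, 0))
  expect_equal(resample_polyline(seg, 10)[, 1], 0:9, tolerance = 1e-12)

  line <- cbind(seq(0, 20, length.out = 15), 0, 0)
  expect_equal(resample_polyline(line, 15), line, tolerance = 1e-12)

  # helix (5 cos t, 5 sin t, 2 t), t in [0, 4 pi]: length 4 pi sqrt(29)
  t <- seq(0, 4 * pi, length.out = 2000)
  helix <- cbind(5 * cos(t), 5 * sin(t), 2 * t)
  r <- resample_polyline(helix, 100)
  arc <- sum(sqrt(rowSums(diff(r)^2)))
  expect_equal(arc, 4 * pi * sqrt(29), tolerance = 0.01 * 4 * pi * sqrt(29))
  # endpoints preserved
  expect_equal(r[1, ], helix[1, ]); expect_equal(r[100, ], helix[2000, ])

  expect_error(resample_polyline(rbind(c(1, 1, 1), c(1, 1, 1)), 5),
               "zero-length")
})

test_that("centroid: single member, symmetry, brute-force equivalence", {
  s <- cbind(seq(0, 30, length.out = 12), sin(seq(0, 3, length.out = 12)), 0)
  one <- streamline_bundle(list(s), "one")
  cen <- bundle_centroid(one)
  expect_equal(cen$points, resample_polyline(s, 101))
  expect_equal(cen$n_segments, 100L)

  # three parallel lines at offsets -1, 0, +1: the middle one wins
  base <- cbind(seq(0, 40, length.out = 20), 0, 0)
  par3 <- streamline_bundle(list(sweep(base, 2, c(0, -1, 0), "+"), base,
                                 sweep(base, 2, c(0, 1, 0), "+")), "p")
  expect_equal(bundle_centroid(par3)$index, 2L)

  # brute force on 15 random streamlines
  set.seed(5)
  b <- streamline_bundle(lapply(1:15, function(i) random_streamline()), "r")
  cen <- bundle_centroid(b)
  rs <- lapply(b$streamlines, resample_polyline, n_points = 101)
  D <- sapply(rs, function(a) sapply(rs, function(bb) bf_mdf(a, bb)))
  expect_equal(cen$index, which.min(rowSums(D) / (length(rs) - 1)))

  expect_error(bundle_centroid(structure(list(name = "e", streamlines = list()),
                                         class = "streamline_bundle")),
               "empty|centroid")
})

test_that("orientation: reversed streamlines are flipped back, idempotent", {
  set.seed(6)
  b <- straight_bundle(n_streamlines = 12, dispersion = 0.5, seed = 6)
  # reverse half of them
  mixed <- b$streamlines
  for (i in seq(1, 12, by = 2))
    mixed[[i]] <- mixed[[i]][nrow(mixed[[i]]):1, , drop = FALSE]
  bm <- streamline_bundle(mixed, "m")
  cen <- bundle_centroid(b)
  fixed <- orient_bundle(bm, cen)
  firsts <- t(sapply(fixed$streamlines, function(s) s[1, ]))
  expect_lt(max(firsts[, 1]), 5)  # all first points at the x = 0 end

  # idempotent
  again <- orient_bundle(fixed, cen)
  expect_equal(again$streamlines, fixed$streamlines)

  # orientation never increases the corresponding-point distance
  for (i in seq_along(fixed$streamlines)) {
    r_or <- resample_polyline(fixed$streamlines[[i]], 101)
    r_in <- resample_polyline(mixed[[i]], 101)
    d_or <- mean(sqrt(rowSums((r_or - cen$points)^2)))
    d_in <- mean(sqrt(rowSums((r_in - cen$points)^2)))
    expect_lte(d_or, d_in + 1e-12)
  }
})

test_that("segment assignment: identity, stability, brute force", {
  s <- cbind(seq(0, 50, length.out = 30), cos(seq(0, 2, length.out = 30)), 0)
  b <- streamline_bundle(list(s), "c")
  cen <- bundle_centroid(b)
  asg <- assign_segments(b, cen)
  expect_equal(asg[[1]], 0:99)

  # small lateral translation keeps the identity mapping
  b2 <- streamline_bundle(list(sweep(s, 2, c(0, 0.1, 0), "+")), "c2")
  expect_equal(assign_segments(b2, cen)[[1]], 0:99)

  # brute-force nearest-midpoint oracle on a random bundle
  set.seed(7)
  br <- streamline_bundle(lapply(1:8, function(i) random_streamline()), "r")
  cenr <- bundle_centroid(br)
  asgr <- assign_segments(orient_bundle(br, cenr), cenr)
  cmid <- (cenr$points[-101, ] + cenr$points[-1, ]) / 2
  orient_br <- orient_bundle(br, cenr)
  for (i in seq_along(orient_br$streamlines)) {
    r <- resample_polyline(orient_br$streamlines[[i]], 101)
    mid <- (r[-101, ] + r[-1, ]) / 2
    bf <- apply(mid, 1, function(p)
      which.min(colSums((t(cmid) - p)^2)) - 1L)
    expect_equal(asgr[[i]], unname(bf))
  }
})

test_that("profiles: uniform field is constant, analytic field is recovered", {
  mesh <- sphere_mesh(2L)
  b <- straight_bundle(n_streamlines = 15, dispersion = 0.8, points = 30,
                       seed = 8)
  cen <- bundle_centroid(b)

  # constant-AFD filled field -> constant profile
  f_const <- filled_fod_field(function(x) 1.3, mesh = mesh)
  prof <- tract_profile(b, cen, f_const, "afd", mesh = mesh)
  expect_true(all(abs(prof - 1.3) < 0.02))

  # linearly varying field f(x) = 1 + 0.02 x recovered at segment midpoints
  f_lin <- filled_fod_field(function(x) 1 + 0.02 * x, mesh = mesh)
  prof_lin <- tract_profile(b, cen, f_lin, "afd", mesh = mesh)
  mids_x <- (cen$points[-101, 1] + cen$points[-1, 1]) / 2
  expected <- 1 + 0.02 * mids_x
  # interior segments, interpolation-level tolerance
  expect_lt(max(abs(prof_lin - expected)[5:95] / expected[5:95]), 0.03)

  # profile direction follows the centroid orientation
  cen_flip <- cen
  cen_flip$points <- cen$points[101:1, ]
  prof_flip <- tract_profile(b, cen_flip, f_lin, "afd", mesh = mesh)
  expect_lt(max(abs(prof_flip - rev(prof_lin))[5:95]), 0.02)
})

test_that("flip invariance: reversing stored streamlines leaves profiles intact", {
  mesh <- sphere_mesh(2L)
  b <- straight_bundle(n_streamlines = 10, dispersion = 0.8, points = 25,
                       seed = 9)
  cen <- bundle_centroid(b)
  f <- filled_fod_field(function(x) 1 + 0.02 * x, mesh = mesh)
  p1 <- tract_profile(b, cen, f, "afd", mesh = mesh)
  rev_b <- streamline_bundle(lapply(b$streamlines,
                                    function(s) s[nrow(s):1, ]), b$name)
  p2 <- tract_profile(rev_b, cen, f, "afd", mesh = mesh)
  expect_equal(p1, p2, tolerance = 1e-10)
})

test_that("z-normalization: moments, degeneracy guard, affine invariance", {
  set.seed(10)
  m <- matrix(rnorm(6 * 100, 5, 2), 6)
  z <- znorm_profiles(m)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(stats::sd(as.numeric(z)), 1, tolerance = 1e-12)
  expect_false(attr(z, "degenerate"))

  zc <- znorm_profiles(matrix(7, 4, 100))
  expect_true(all(zc == 0))
  expect_true(attr(zc, "degenerate"))

  z2 <- znorm_profiles(3.2 * m - 11)
  expect_equal(unclass(z)[, ], unclass(z2)[, ], tolerance = 1e-10)
})
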