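test_that("confound regression: orthogonality, perfect fit, rank errors", {
  set.seed(1)
  Y <- matrix(rnorm(38 * 20), 38)
  X <- matrix(rnorm(38 * 3), 38,
              dimnames = list(NULL, c("hl", "thi", "dur")))
  R <- regress_confounds(Y, X)
  # residuals (about their means) orthogonal to every confound column
  expect_lt(max(abs(crossprod(X, sweep(R, 2, colMeans(R))))), 1e-8)
  # grand mean preserved
  expect_equal(colMeans(R), colMeans(Y), tolerance = 1e-12)

  # Y = 2 HL exactly -> adjusted values constant at the grand mean
  Y2 <- matrix(2 * X[, 1], 38, 4)
  R2 <- regress_confounds(Y2, X)
  expect_equal(unname(R2), matrix(colMeans(Y2), 38, 4, byrow = TRUE),
               tolerance = 1e-10)

  expect_error(regress_confounds(Y, cbind(X, X[, 1])), "rank deficient")
})

test_that("two-sample t: hand-computed oracle, antisymmetry, degeneracy", {
  Y <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 1)
  g <- factor(rep(c("a", "b"), each = 3))
  r <- ttest_segments(Y, g)
  expect_equal(r$t, 3 / sqrt(2 / 3), tolerance = 1e-12)  # 3.674, b - a
  expect_equal(r$df, 4)

  # swapping labels negates t, p unchanged
  r2 <- ttest_segments(Y, factor(rep(c("b", "a"), each = 3),
                                 levels = c("a", "b")))
  expect_equal(r2$t, -r$t)
  expect_equal(r2$p, r$p)

  # identical groups: t ~ 0
  Yn <- matrix(rep(c(1, 2, 3), 2), ncol = 1)
  expect_equal(ttest_segments(Yn, g)$t, 0, tolerance = 1e-12)

  # zero pooled variance flagged
  rz <- ttest_segments(matrix(1, 6, 1), g)
  expect_equal(rz$t, 0); expect_equal(rz$p, 1); expect_true(rz$degenerate)
})

test_that("permutation FWE matches exhaustive enumeration on 4+4 subjects", {
  set.seed(2)
  Y <- matrix(rnorm(8), ncol = 1)
  g <- factor(rep(c("a", "b"), each = 4))
  fw <- permutation_fwe(list(b1 = Y), g,
                        stats_config(n_permutations = 5000,
                                     n_metrics_bonferroni = 1))
  expect_true(fw$exhaustive)
  # manual enumeration over all choose(8, 4) = 70 assignments
  tt <- ttest_segments(Y, g)$t
  sets <- combn(8, 4)
  mt <- apply(sets, 2, function(ix) {
    gg <- factor(ifelse(seq_len(8) %in% ix, "a", "b"), levels = c("a", "b"))
    abs(ttest_segments(Y, gg)$t)
  })
  expect_equal(fw$stats$p_fwe, mean(mt >= abs(tt) - 1e-12))
})

test_that("permutation FWE: boundary p, determinism, monotonicity", {
  set.seed(3)
  n <- 20
  Y <- matrix(rnorm(n * 30), n)
  Y[11:20, 5] <- Y[11:20, 5] + 50  # one overwhelming effect
  g <- factor(rep(c("a", "b"), each = 10))
  cfg <- stats_config(n_permutations = 200, n_metrics_bonferroni = 1,
                      seed = 9)
  fw <- permutation_fwe(list(b = Y), g, cfg)
  # observed |t| beats every sampled permutation: p = 1 / (B + 1)
  expect_equal(fw$stats$p_fwe[5], 1 / 201)

  # identical seed, identical p values to the last bit
  fw2 <- permutation_fwe(list(b = Y), g, cfg)
  expect_identical(fw$stats$p_fwe, fw2$stats$p_fwe)

  # p_fwe non-increasing in |t|
  ord <- order(abs(fw$stats$t))
  expect_true(all(diff(fw$stats$p_fwe[ord]) <= 1e-12))
  # and never below the uncorrected p
  expect_true(all(fw$stats$p_fwe >= fw$stats$p_uncorrected - 1e-15))
})

test_that("ANCOVA statistic equals lm() partial t and stays calibrated", {
  set.seed(4)
  n <- 24
  X <- cbind(hl = rnorm(n), thi = c(rep(0, 12), abs(rnorm(12, 10, 4))))
  g <- factor(rep(c("ctl", "tin"), each = 12))
  Y <- matrix(rnorm(n * 6), n)
  fw <- permutation_fwe(list(b = Y), g,
                        stats_config(n_permutations = 50,
                                     n_metrics_bonferroni = 1, seed = 1),
                        confounds = X)
  for (j in 1:6) {
    fit <- summary(lm(Y[, j] ~ X + g))$coefficients
    expect_equal(fw$stats$t[j], fit["gtin", "t value"], tolerance = 1e-10)
  }
})

test_that("cluster filtering reproduces run-length semantics", {
  mk <- function(mask) data.frame(bundle = "b",
                                  segment = seq_along(mask) - 1L,
                                  significant = as.logical(mask),
                                  p_uncorrected = runif(length(mask)),
                                  t = rnorm(length(mask)))
  # 00111110 with extent 5: one cluster spanning segments 2..6
  cl <- cluster_filter(mk(c(0, 0, 1, 1, 1, 1, 1, 0)), 5)
  expect_equal(nrow(cl), 1)
  expect_equal(c(cl$start, cl$end, cl$extent), c(2, 6, 5))

  # 0110: dropped at extent 5, kept at extent 2
  expect_equal(nrow(cluster_filter(mk(c(0, 1, 1, 0)), 5)), 0)
  expect_equal(nrow(cluster_filter(mk(c(0, 1, 1, 0)), 2)), 1)

  # random masks against a brute-force run-length scan
  set.seed(5)
  for (i in 1:20) {
    mask <- runif(60) < 0.4
    df <- mk(mask)
    for (ext in c(2, 5)) {
      cl <- cluster_filter(df, ext)
      r <- rle(mask)
      expected <- sum(r$values & r$lengths >= ext)
      expect_equal(nrow(cl), expected)
      if (nrow(cl) > 0) {
        expect_true(all(cl$extent >= ext))
        # every cluster is genuinely maximal: flanked by non-significant
        for (k in seq_len(nrow(cl))) {
          if (cl$start[k] > 0) expect_false(mask[cl$start[k]])
          if (cl$end[k] < 59) expect_false(mask[cl$end[k] + 2])
        }
      }
    }
  }
})

test_that("effect sizes: d from t reproduces published rows, f2 formula", {
  ref <- reference_group_differences()
  expect_equal(nrow(ref), 18L)
  d <- cohens_d_from_t(ref$t, 19, 19)
  expect_equal(round(d, 3), ref$d)

  expect_equal(cohens_d_from_t(0, 10, 10), 0)
  expect_equal(cohens_f2(0), 0)
  expect_equal(cohens_f2(0.545), 0.545^2 / (1 - 0.545^2), tolerance = 1e-12)
  expect_warning(v <- cohens_f2(1), "infinite")
  expect_true(is.infinite(v))
})

test_that("post-hoc power: null case, monotonicity, frozen simulation value", {
  expect_equal(posthoc_power(0, 19, 19, 0.05), 0.05, tolerance = 1e-12)
  d <- seq(0, 3, by = 0.25)
  pw <- posthoc_power(d, 19, 19, 0.05)
  expect_true(all(diff(pw) > 0))
  expect_true(all(pw >= 0 & pw <= 1))
  # 1e6-replicate Monte-Carlo rejection rate for d = 1, n = 19 + 19,
  # alpha = .05 (computed once with a fixed seed): 0.850737
  expect_equal(posthoc_power(1, 19, 19, 0.05), 0.850737, tolerance = 0.005)
  expect_error(posthoc_power(1, 19, 19, alpha = 1.2), "alpha")
})

test_that("semi-partial correlation matches the normal-equations oracle", {
  # metric driven purely by the cofactor: r = 1
  set.seed(6)
  X <- cbind(hl = rnorm(8, 20, 5), thi = rnorm(8, 15, 6))
  Y1 <- matrix(3 * X[, "hl"], ncol = 1)
  expect_equal(semipartial_correlation(Y1, X, "hl"), 1, tolerance = 1e-10)

  # algebraic oracle on a small worked dataset
  Y <- matrix(rnorm(8 * 3), 8)
  r <- semipartial_correlation(Y, X, "hl")
  beta <- solve(crossprod(cbind(1, X)), crossprod(cbind(1, X), Y))
  adj <- Y - X[, "thi", drop = FALSE] %*% beta[3, , drop = FALSE]
  expect_equal(r, drop(cor(X[, "hl"], adj)), tolerance = 1e-10)

  # orthogonal cofactor: r ~ 0 at large n
  set.seed(7)
  Xl <- cbind(hl = rnorm(4000), thi = rnorm(4000))
  Yl <- matrix(rnorm(4000), ncol = 1)
  expect_lt(abs(semipartial_correlation(Yl, Xl, "hl")), 0.05)

  expect_error(semipartial_correlation(Y, cbind(hl = rep(1, 8),
                                                thi = X[, 2]), "hl"),
               "constant|rank")
})

test_that("correlation p-values follow the t-transform", {
  expect_equal(correlation_pvalue(0, 20), 1)
  expect_equal(correlation_pvalue(0.545, 38), 4.030909e-4, tolerance = 1e-6)
  rr <- seq(0.1, 0.99, by = 0.05)
  expect_true(all(diff(correlation_pvalue(rr, 30)) < 0))
})

test_that("correlation FWE flags a real cofactor association", {
  set.seed(8)
  n <- 38
  X <- cbind(hl_db = abs(rnorm(n, 17, 8)), thi = abs(rnorm(n, 8, 8)),
             duration_y = abs(rnorm(n, 6, 6)))
  Y <- matrix(rnorm(n * 50, 1, 0.1), n)
  Y[, 10:14] <- Y[, 10:14] + 0.02 * X[, "hl_db"]   # strong HL association
  res <- correlation_fwe(list(b = Y), X, "hl_db",
                         stats_config(n_permutations = 300,
                                      n_metrics_bonferroni = 1, seed = 2))
  expect_true(all(res$stats$significant[10:14]))
  expect_lt(mean(res$stats$significant[-(10:14)]), 0.1)
  expect_true(all(res$stats$r >= -1 & res$stats$r <= 1))
  expect_true(all(res$stats$f2 >= 0))
  expect_equal(res$stats$n, rep(n, 50))
})

test_that("group comparison models: conservative, calibrated, powered", {
  # residualize-then-test with structural group proxies never anti-conservative
  cs <- cohort_spec(seed = 77)
  pc <- make_profile_cohort(cs)
  cfg <- stats_config(n_permutations = 300, n_metrics_bonferroni = 1,
                      seed = 5)
  res_r <- group_comparison(pc$profiles, pc$cohort, cfg,
                            confound_model = "residualize")
  res_n <- group_comparison(pc$profiles, pc$cohort, cfg,
                            confound_model = "none")
  res_a <- group_comparison(pc$profiles, pc$cohort, cfg,
                            confound_model = "ancova")
  # on a null cohort none of the three models reports anything significant
  expect_false(any(res_r$segments$significant))
  expect_false(any(res_n$segments$significant))
  expect_false(any(res_a$segments$significant))
  # residualization on group-proxy confounds shrinks observed |t|
  expect_lt(max(abs(res_r$segments$t)), max(abs(res_n$segments$t)) + 1)

  # injected effect is recovered with a correctly-placed cluster
  cs2 <- cohort_spec(seed = 78, effect_windows = list(
    list(bundle = "bundleA", metric = "afd", start = 40, end = 59,
         delta = 3)))
  pc2 <- make_profile_cohort(cs2)
  res2 <- group_comparison(pc2$profiles, pc2$cohort, cfg,
                           confound_model = "none")
  cl <- res2$clusters
  expect_gt(nrow(cl[cl$bundle == "bundleA", ]), 0)
  ov <- cl[cl$bundle == "bundleA" & cl$start <= 59 & cl$end >= 40, ]
  expect_gt(nrow(ov), 0)
  expect_true(all(c("d", "power") %in% names(cl)))
  expect_true(all(cl$power >= 0 & cl$power <= 1))
})
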