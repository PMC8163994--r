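#' Regress confounds out of a profile matrix
#'
#' Per-segment ordinary least squares of the metric on an intercept plus the
#' confound columns; returns the residuals with the grand mean re-added, so
#' that group contrasts act on confound-adjusted metric values on the
#' original scale. Fitted on the pooled sample with the group label excluded
#' from the design (residualize-then-test); pass the group as an extra
#' column of `X` for the joint alternative.
#'
#' @param Y Subjects x segments numeric matrix (a [profile_matrix()]).
#' @param X Subjects x k confound matrix (no intercept column; one is
#'   added). Typically hearing loss, THI and tinnitus duration.
#' @return Matrix like `Y` of adjusted values.
#' @export
regress_confounds <- function(Y, X) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  stopifnot(nrow(Y) == nrow(X))
  design <- cbind(`(Intercept)` = 1, X)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    bad <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    stop("confound design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  resid <- Y - design %*% qr.coef(qrd, Y)
  sweep(resid, 2, colMeans(Y), "+")
}

#' Segment-wise two-sample t-tests
#'
#' Pooled-variance (Student) two-sample t per segment with
#' `df = n1 + n2 - 2`, two-sided p from the t distribution. The statistic
#' is `mean(group2) - mean(group1)` over the pooled standard error, where
#' `group2` is the second factor level. Zero pooled variance gives t = 0,
#' p = 1 (flagged via the `degenerate` attribute).
#'
#' @param Y Subjects x segments matrix (typically confound-adjusted).
#' @param groups Factor (or coercible) of length `nrow(Y)` with exactly 2
#'   levels, each with >= 2 subjects.
#' @return List with `t`, `p` (length = segments), `df`, and attribute-like
#'   entries `n1`, `n2`.
#' @export
ttest_segments <- function(Y, groups) {
  Y <- as.matrix(Y)
  groups <- as.factor(groups)
  stopifnot(nlevels(groups) == 2, all(table(groups) >= 2))
  g2 <- groups == levels(groups)[2]
  n1 <- sum(!g2); n2 <- sum(g2); df <- n1 + n2 - 2
  m1 <- colMeans(Y[!g2, , drop = FALSE])
  m2 <- colMeans(Y[g2, , drop = FALSE])
  ss1 <- colSums(sweep(Y[!g2, , drop = FALSE], 2, m1)^2)
  ss2 <- colSums(sweep(Y[g2, , drop = FALSE], 2, m2)^2)
  sp2 <- (ss1 + ss2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  degen <- se == 0
  t <- ifelse(degen, 0, (m2 - m1) / ifelse(degen, 1, se))
  p <- ifelse(degen, 1, 2 * stats::pt(-abs(t), df))
  list(t = t, p = p, df = df, n1 = n1, n2 = n2, degenerate = degen)
}

#' Statistical configuration for the group analysis
#'
#' @param n_permutations Label permutations for the FWE correction
#'   (default 5000).
#' @param alpha Family-wise significance level (default 0.05).
#' @param n_metrics_bonferroni The alpha is pre-divided by this count of
#'   metrics analyzed in parallel (default 3: AFD, peak amplitude, FA).
#' @param cluster_extent_min Minimum run of contiguous significant segments
#'   for a finding to be kept (default 5; 2 reproduces the lenient
#'   supplementary variant).
#' @param power_alpha Alpha used for post-hoc power (default 0.05,
#'   two-sided; deliberately configurable because published power values
#'   are often computed at a corrected, data-dependent threshold).
#' @param seed RNG seed for the permutations.
#' @return Object of class `stats_config`.
#' @export
stats_config <- function(n_permutations = 5000L, alpha = 0.05,
                         n_metrics_bonferroni = 3L, cluster_extent_min = 5L,
                         power_alpha = 0.05, seed = 1L) {
  stopifnot(n_permutations >= 1, alpha > 0, alpha < 1,
            cluster_extent_min >= 1, power_alpha > 0, power_alpha < 1)
  structure(list(n_permutations = as.integer(n_permutations), alpha = alpha,
                 n_metrics_bonferroni = as.integer(n_metrics_bonferroni),
                 cluster_extent_min = as.integer(cluster_extent_min),
                 power_alpha = power_alpha, seed = as.integer(seed)),
            class = "stats_config")
}

# All distinct assignments of n1 subjects (out of n) to group 1, as a
# permutation-index matrix compatible with random label permutations.
exhaustive_group1_sets <- function(n, n1) {
  utils::combn(n, n1)
}

#' maxT permutation family-wise error correction
#'
#' For each permutation the group labels are randomly reassigned and the
#' maximum |t| over all bundles and segments of the run is recorded; each
#' segment's corrected p-value is the add-one proportion
#' `(b + 1) / (B + 1)` of permutations whose maximum reaches its observed
#' |t| (Westfall-Young / Nichols-Holmes maxT), which controls the
#' family-wise error over the whole segment family. If the requested number
#' of permutations is at least the number of distinct label assignments,
#' the null distribution is enumerated exactly instead.
#'
#' @param Y_list Named list of subjects x segments matrices, one per bundle
#'   (one metric run); confound-adjusted upstream, or raw when `confounds`
#'   is given.
#' @param groups Two-level factor of subjects (same order in every matrix).
#' @param cfg A [stats_config()].
#' @param confounds Optional subjects x k confound matrix. When supplied,
#'   the per-segment statistic is the partial t of the group term in the
#'   ANCOVA `Y ~ 1 + confounds + group` (via Frisch-Waugh projection), whose
#'   standard error accounts for group-confound collinearity; permutations
#'   permute the group labels against the fixed confounds. When `NULL`, the
#'   statistic is the pooled-variance two-sample t.
#' @return Object of class `fwe_result`: list with `stats` (data frame:
#'   bundle, segment (0-based), t, p_uncorrected, p_fwe, significant),
#'   `alpha_corrected` (alpha / n_metrics_bonferroni), `t_threshold` (the
#'   permutation-quantile |t| cutoff), `p_threshold` (that cutoff mapped to
#'   an uncorrected two-sided p), `max_t_distribution`, `exhaustive`.
#' @export
permutation_fwe <- function(Y_list, groups, cfg = stats_config(),
                            confounds = NULL) {
  if (inherits(Y_list, "matrix")) Y_list <- list(bundle = Y_list)
  groups <- as.factor(groups)
  stopifnot(nlevels(groups) == 2)
  bundles <- names(Y_list)
  if (is.null(bundles)) bundles <- paste0("bundle", seq_along(Y_list))
  ncols <- vapply(Y_list, ncol, integer(1))
  Y <- do.call(cbind, lapply(Y_list, as.matrix))
  n <- nrow(Y)
  g2 <- groups == levels(groups)[2]
  n1 <- sum(!g2); n2 <- sum(g2)

  if (is.null(confounds)) {
    df <- n1 + n2 - 2
    col_t <- function(sel1) {
      # pooled two-sample t for all columns given a logical group-1 selector
      m1 <- colMeans(Y[sel1, , drop = FALSE])
      m2 <- colMeans(Y[!sel1, , drop = FALSE])
      ss1 <- pmax(colSums(Y[sel1, , drop = FALSE]^2) - n1 * m1^2, 0)
      ss2 <- pmax(colSums(Y[!sel1, , drop = FALSE]^2) - n2 * m2^2, 0)
      se <- sqrt((ss1 + ss2) / df * (1 / n1 + 1 / n2))
      ifelse(se == 0, 0, (m2 - m1) / ifelse(se == 0, 1, se))
    }
  } else {
    X <- cbind(1, as.matrix(confounds))
    stopifnot(nrow(X) == n)
    df <- n - ncol(X) - 1
    # Frisch-Waugh: project Y and the (permuted) group indicator off the
    # confound space once; the partial t of group falls out of the projected
    # quantities.
    Mproj <- diag(n) - X %*% solve(crossprod(X), t(X))
    Yt <- Mproj %*% Y
    Yss <- colSums(Yt^2)
    col_t <- function(sel1) {
      gt <- Mproj %*% as.numeric(!sel1)   # indicator of group 2
      gss <- sum(gt^2)
      if (gss < 1e-12) return(rep(0, ncol(Y)))
      beta <- drop(crossprod(gt, Yt)) / gss
      rss <- pmax(Yss - beta^2 * gss, 0)
      se <- sqrt(rss / df / gss)
      ifelse(se == 0, 0, beta / ifelse(se == 0, 1, se))
    }
  }

  obs_t <- col_t(!g2)
  n_assign <- choose(n, n1)
  exhaustive <- cfg$n_permutations >= n_assign
  if (exhaustive) {
    sets <- exhaustive_group1_sets(n, n1)
    maxT <- apply(sets, 2, function(ix) {
      sel <- rep(FALSE, n); sel[ix] <- TRUE
      max(abs(col_t(sel)))
    })
    B <- length(maxT)
    # the identity assignment is one column of the enumeration, so the
    # add-one numerator is already included
    p_fwe_of <- function(tv) sapply(abs(tv), function(a) mean(maxT >= a - 1e-12))
    t_threshold <- stats::quantile(maxT, 1 - cfg$alpha / cfg$n_metrics_bonferroni,
                                   type = 1, names = FALSE)
  } else {
    B <- cfg$n_permutations
    maxT <- with_seed(cfg$seed, {
      vapply(seq_len(B), function(b) {
        sel <- rep(FALSE, n); sel[sample.int(n, n1)] <- TRUE
        max(abs(col_t(sel)))
      }, numeric(1))
    })
    p_fwe_of <- function(tv)
      sapply(abs(tv), function(a) (sum(maxT >= a - 1e-12) + 1) / (B + 1))
    t_threshold <- stats::quantile(maxT, 1 - cfg$alpha / cfg$n_metrics_bonferroni,
                                   type = 8, names = FALSE)
  }
  # p_uncorrected is the parametric two-sided p; in multi-segment runs the
  # permutation-FWE p dominates it, but with very few tests the discrete
  # permutation p can legitimately dip below the parametric value, so no
  # clamping is applied.
  p_unc <- 2 * stats::pt(-abs(obs_t), df)
  p_fwe <- p_fwe_of(obs_t)
  alpha_corr <- cfg$alpha / cfg$n_metrics_bonferroni
  stats_df <- data.frame(
    bundle = rep(bundles, ncols),
    segment = unlist(lapply(ncols, function(k) seq_len(k) - 1L)),
    t = obs_t,
    p_uncorrected = p_unc,
    p_fwe = p_fwe,
    significant = p_fwe < alpha_corr,
    row.names = NULL, stringsAsFactors = FALSE)
  stats_df$significant <- stats_df$p_fwe < alpha_corr
  structure(list(stats = stats_df, alpha_corrected = alpha_corr,
                 t_threshold = t_threshold,
                 p_threshold = 2 * stats::pt(-t_threshold, df),
                 df = df, n1 = n1, n2 = n2,
                 max_t_distribution = maxT, exhaustive = exhaustive),
            class = "fwe_result")
}

#' @export
print.fwe_result <- function(x, ...) {
  cat("maxT permutation FWE:", length(x$max_t_distribution),
      if (x$exhaustive) "exhaustive assignments," else "permutations,",
      sum(x$stats$significant), "significant segment(s) at alpha =",
      format(x$alpha_corrected), "\n")
  invisible(x)
}

#' Cluster-extent filtering of significant segments
#'
#' Finds maximal runs of contiguous significant segments within each bundle
#' and drops runs shorter than the extent threshold. For each surviving
#' cluster the segment with the smallest p-value is reported.
#'
#' @param stats_df Data frame with columns `bundle`, `segment` (0-based,
#'   contiguous within bundle), `significant`, and optionally
#'   `p_uncorrected` and `t` for the per-cluster minima.
#' @param min_extent Minimum cluster length in segments.
#' @return Data frame with one row per surviving cluster: `bundle`,
#'   `cluster_id`, `start`, `end`, `extent`, `min_p`, `min_p_segment`,
#'   `t_at_min_p`.
#' @export
cluster_filter <- function(stats_df, min_extent = 5L) {
  stopifnot(min_extent >= 1)
  out <- list()
  cid <- 0L
  for (bn in unique(stats_df$bundle)) {
    sub <- stats_df[stats_df$bundle == bn, , drop = FALSE]
    sub <- sub[order(sub$segment), , drop = FALSE]
    r <- rle(as.logical(sub$significant))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in seq_along(r$values)) {
      if (!r$values[k] || r$lengths[k] < min_extent) next
      cid <- cid + 1L
      rows <- starts[k]:ends[k]
      pin <- if ("p_uncorrected" %in% names(sub)) sub$p_uncorrected[rows]
             else rep(NA_real_, length(rows))
      imin <- if (all(is.na(pin))) 1L else which.min(pin)
      out[[cid]] <- data.frame(
        bundle = bn, cluster_id = sprintf("cl%02d", cid),
        start = sub$segment[rows[1]], end = sub$segment[rows[length(rows)]],
        extent = length(rows),
        min_p = pin[imin],
        min_p_segment = sub$segment[rows[imin]],
        t_at_min_p = if ("t" %in% names(sub)) sub$t[rows[imin]] else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(bundle = character(), cluster_id = character(),
                      start = integer(), end = integer(), extent = integer(),
                      min_p = numeric(), min_p_segment = integer(),
                      t_at_min_p = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Cohen's d from a two-sample t statistic
#'
#' For a two-group design, `d = 2 |t| / sqrt(df)` with `df = n1 + n2 - 2`
#' (exact for equal group sizes). The direction of the group difference is
#' carried by the sign of t, reported separately.
#'
#' @param t t statistic (vectorized).
#' @param n1,n2 Group sizes (>= 2).
#' @return Nonnegative effect size(s).
#' @export
cohens_d_from_t <- function(t, n1, n2) {
  stopifnot(n1 >= 2, n2 >= 2)
  2 * abs(t) / sqrt(n1 + n2 - 2)
}

#' Cohen's f-squared from a correlation
#'
#' `f2 = r^2 / (1 - r^2)`; diverges as |r| -> 1 (returns `Inf` with a
#' warning).
#'
#' @param r Correlation(s) in [-1, 1].
#' @return Nonnegative effect size(s).
#' @export
cohens_f2 <- function(r) {
  stopifnot(all(abs(r) <= 1))
  out <- r^2 / (1 - r^2)
  if (any(!is.finite(out))) warning("|r| = 1: f2 is infinite")
  out
}

#' Post-hoc power of a two-sided two-sample t-test
#'
#' Power at effect size d via the noncentral t distribution with
#' noncentrality `d * sqrt(n1 n2 / (n1 + n2))` and `df = n1 + n2 - 2`.
#' At d = 0 the power equals alpha exactly.
#'
#' @param d Cohen's d (vectorized).
#' @param n1,n2 Group sizes.
#' @param alpha Two-sided significance level in (0, 1).
#' @return Power in [0, 1].
#' @export
posthoc_power <- function(d, n1, n2, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  df <- n1 + n2 - 2
  ncp <- abs(d) * sqrt(n1 * n2 / (n1 + n2))
  crit <- stats::qt(1 - alpha / 2, df)
  1 - stats::pt(crit, df, ncp) + stats::pt(-crit, df, ncp)
}

#' Semi-partial correlation of a cofactor with a metric
#'
#' Fits a joint OLS of the metric on all confounds, subtracts from the
#' metric the fitted contributions of the confounds other than the cofactor
#' of interest, and returns the Pearson correlation between the adjusted
#' metric and the cofactor — per segment. (For hearing loss the natural
#' sample is the whole cohort; for THI and tinnitus duration only the
#' tinnitus group carries information.)
#'
#' @param Y Subjects x segments metric matrix (already subset to the sample
#'   of interest; >= 4 subjects).
#' @param confounds Data frame / matrix of all confound columns on the same
#'   sample.
#' @param cofactor Name (or index) of the confound of interest within
#'   `confounds`.
#' @return Numeric vector of per-segment semi-partial correlations.
#' @export
semipartial_correlation <- function(Y, confounds, cofactor) {
  Y <- as.matrix(Y)
  X <- as.matrix(confounds)
  stopifnot(nrow(Y) == nrow(X), nrow(Y) >= 4)
  if (is.character(cofactor)) cofactor <- match(cofactor, colnames(X))
  if (is.na(cofactor) || cofactor < 1 || cofactor > ncol(X))
    stop("cofactor not found among the confound columns")
  x <- X[, cofactor]
  if (stats::sd(x) == 0) stop("cofactor is constant in the selected sample")
  design <- cbind(1, X)
  qrd <- qr(design)
  if (qrd$rank < ncol(design))
    stop("confound design is rank deficient in the selected sample")
  beta <- qr.coef(qrd, Y)                       # (1 + k) x segments
  others <- setdiff(seq_len(ncol(X)), cofactor)
  adj <- Y - X[, others, drop = FALSE] %*% beta[1 + others, , drop = FALSE]
  drop(stats::cor(x, adj))
}

#' Permutation FWE correction for per-segment correlations
#'
#' maxT-style correction for [semipartial_correlation()]: the cofactor
#' values are permuted across subjects, the maximum |r| over all bundles
#' and segments is recorded per permutation, and add-one corrected p-values
#' are returned.
#'
#' @param Y_list Named list of per-bundle metric matrices (same subjects).
#' @param confounds Confound data frame on the same subjects.
#' @param cofactor Column of interest.
#' @param cfg A [stats_config()].
#' @return Object of class `correlation_result`: data frame `stats` with
#'   `bundle`, `segment`, `r`, `f2`, `p_fwe`, `n`, plus `alpha_corrected`.
#' @export
correlation_fwe <- function(Y_list, confounds, cofactor, cfg = stats_config()) {
  if (inherits(Y_list, "matrix")) Y_list <- list(bundle = Y_list)
  bundles <- names(Y_list)
  if (is.null(bundles)) bundles <- paste0("bundle", seq_along(Y_list))
  ncols <- vapply(Y_list, ncol, integer(1))
  n <- nrow(Y_list[[1]])
  obs_r <- unlist(lapply(Y_list, semipartial_correlation, confounds, cofactor))
  X <- as.matrix(confounds)
  if (is.character(cofactor)) cof_i <- match(cofactor, colnames(X)) else cof_i <- cofactor
  perm_max <- with_seed(cfg$seed, {
    vapply(seq_len(cfg$n_permutations), function(b) {
      Xp <- X
      Xp[, cof_i] <- X[sample.int(n), cof_i]
      max(abs(unlist(lapply(Y_list, function(Y)
        semipartial_correlation(Y, Xp, cof_i)))))
    }, numeric(1))
  })
  p_fwe <- sapply(abs(obs_r), function(a)
    (sum(perm_max >= a - 1e-12) + 1) / (cfg$n_permutations + 1))
  alpha_corr <- cfg$alpha / cfg$n_metrics_bonferroni
  structure(list(
    stats = data.frame(
      bundle = rep(bundles, ncols),
      segment = unlist(lapply(ncols, function(k) seq_len(k) - 1L)),
      r = obs_r, f2 = cohens_f2(pmin(abs(obs_r), 1 - 1e-12) * sign(obs_r)),
      p_fwe = p_fwe, n = n,
      significant = p_fwe < alpha_corr,
      row.names = NULL, stringsAsFactors = FALSE),
    alpha_corrected = alpha_corr),
    class = "correlation_result")
}

#' Parametric p-value of a Pearson correlation
#'
#' Two-sided p from `t = r sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom.
#'
#' @param r Correlation(s).
#' @param n Sample size (> 2).
#' @return Two-sided p-value(s).
#' @export
correlation_pvalue <- function(r, n) {
  stopifnot(n > 2, all(abs(r) <= 1))
  t <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(-abs(t), n - 2)
}

#' Full group comparison for one metric across bundles
#'
#' The complete per-metric analysis: confound regression
#' (residualize-then-test), segment-wise pooled-t group comparison, maxT
#' permutation FWE correction, cluster-extent filtering, Cohen's d and
#' post-hoc power. The returned segment table is the per-segment analogue
#' of a published along-tract findings table: per cluster, the minimum
#' uncorrected p, its segment, t, d and power.
#'
#' @param Y_list Named list of per-bundle subjects x segments matrices.
#' @param cohort Cohort data frame with columns `group`, `hl_db`, `thi`,
#'   `duration_y` (see [sample_cohort_table()]).
#' @param cfg A [stats_config()].
#' @param confound_cols Confound columns regressed before testing (ignored
#'   when `confound_model = "none"`).
#' @param confound_model How confounds enter the group test.
#'   `"residualize"` (default): confound slopes fitted on the pooled sample
#'   with the group label excluded, then a two-sample t on the residuals —
#'   the published order of operations; conservative when a confound is a
#'   structural group proxy (THI and duration are 0 for every control).
#'   `"ancova"`: partial t of the group term with the confounds in the
#'   model (calibrated under group-confound collinearity, at the price of
#'   power against effects shared with the proxies). `"none"`: two-sample
#'   t on the profiles as given.
#' @return List with `segments` (per-segment stats incl. d and power),
#'   `clusters` (cluster table with effect sizes at the min-p segment),
#'   `fwe` (the [permutation_fwe()] result).
#' @export
group_comparison <- function(Y_list, cohort, cfg = stats_config(),
                             confound_cols = c("hl_db", "thi", "duration_y"),
                             confound_model = c("residualize", "ancova",
                                                "none")) {
  confound_model <- match.arg(confound_model)
  if (inherits(Y_list, "matrix")) Y_list <- list(bundle = Y_list)
  if (confound_model == "none") {
    fwe <- permutation_fwe(Y_list, cohort$group, cfg)
  } else {
    X <- as.matrix(cohort[, confound_cols, drop = FALSE])
    if (confound_model == "residualize") {
      adj <- lapply(Y_list, function(Y) regress_confounds(Y, X))
      fwe <- permutation_fwe(adj, cohort$group, cfg)
    } else {
      fwe <- permutation_fwe(Y_list, cohort$group, cfg, confounds = X)
    }
  }
  seg <- fwe$stats
  seg$d <- cohens_d_from_t(seg$t, fwe$n1, fwe$n2)
  seg$direction <- ifelse(seg$t >= 0, "group2_higher", "group2_lower")
  seg$power <- posthoc_power(seg$d, fwe$n1, fwe$n2, cfg$power_alpha)
  clusters <- cluster_filter(seg, cfg$cluster_extent_min)
  if (nrow(clusters) > 0) {
    clusters$d <- cohens_d_from_t(clusters$t_at_min_p, fwe$n1, fwe$n2)
    clusters$power <- posthoc_power(clusters$d, fwe$n1, fwe$n2,
                                    cfg$power_alpha)
  }
  list(segments = seg, clusters = clusters, fwe = fwe)
}
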