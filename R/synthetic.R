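# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic streamline bundle
#'
#' @param name Bundle label.
#' @param centerline_control_points m x 3 matrix of control points (mm)
#'   through which the bundle's smooth centerline is splined; at least 2
#'   distinct points.
#' @param n_streamlines Number of streamlines (default 500, a desk-scale
#'   stand-in for the thousands produced by probabilistic tracking).
#' @param radial_dispersion_mm Standard deviation of the per-streamline
#'   radial offset from the centerline (>= 0).
#' @param points_per_streamline Points per generated streamline (>= 2).
#' @param jitter_mm Per-point positional jitter sd; default 5% of the
#'   radial dispersion.
#' @param seed RNG seed; the bundle is a pure function of the spec.
#' @return Object of class `bundle_spec`.
#' @export
bundle_spec <- function(name, centerline_control_points, n_streamlines = 500L,
                        radial_dispersion_mm = 2, points_per_streamline = 100L,
                        jitter_mm = 0.05 * radial_dispersion_mm, seed = 1L) {
  pts <- rbind(centerline_control_points)
  if (nrow(unique(pts)) < 2)
    stop("centerline needs at least 2 distinct control points")
  stopifnot(n_streamlines >= 1, radial_dispersion_mm >= 0,
            points_per_streamline >= 2, jitter_mm >= 0)
  structure(list(name = name, centerline_control_points = pts,
                 n_streamlines = as.integer(n_streamlines),
                 radial_dispersion_mm = radial_dispersion_mm,
                 points_per_streamline = as.integer(points_per_streamline),
                 jitter_mm = jitter_mm, seed = as.integer(seed)),
            class = "bundle_spec")
}

# Smooth centerline through control points: natural cubic spline per
# coordinate over cumulative chord length, evaluated densely.
spline_centerline <- function(control_points, n_dense = 200L) {
  cp <- rbind(control_points)
  if (nrow(cp) == 2) {
    tt <- seq(0, 1, length.out = n_dense)
    return(cbind(cp[1, 1] + tt * (cp[2, 1] - cp[1, 1]),
                 cp[1, 2] + tt * (cp[2, 2] - cp[1, 2]),
                 cp[1, 3] + tt * (cp[2, 3] - cp[1, 3])))
  }
  s <- c(0, cumsum(sqrt(rowSums(diff(cp)^2))))
  sq <- seq(0, s[length(s)], length.out = n_dense)
  sapply(1:3, function(k) stats::spline(s, cp[, k], xout = sq)$y)
}

# Orthonormal frame (tangent, n1, n2) along a polyline; tangents by central
# differences, normals propagated to avoid frame flips.
frame_along <- function(pts) {
  n <- nrow(pts)
  tan <- rbind(pts[2, ] - pts[1, ],
               (pts[3:n, , drop = FALSE] - pts[1:(n - 2), , drop = FALSE]) / 2,
               pts[n, ] - pts[n - 1, ])
  tan <- tan / pmax(sqrt(rowSums(tan^2)), 1e-12)
  ref <- if (abs(tan[1, 3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  n1 <- matrix(0, n, 3); n2 <- matrix(0, n, 3)
  v <- ref - sum(ref * tan[1, ]) * tan[1, ]
  v <- v / sqrt(sum(v^2))
  for (i in seq_len(n)) {
    if (i > 1) {
      v <- n1[i - 1, ] - sum(n1[i - 1, ] * tan[i, ]) * tan[i, ]
      v <- v / sqrt(sum(v^2))
    }
    n1[i, ] <- v
    n2[i, ] <- c(tan[i, 2] * v[3] - tan[i, 3] * v[2],
                 tan[i, 3] * v[1] - tan[i, 1] * v[3],
                 tan[i, 1] * v[2] - tan[i, 2] * v[1])
  }
  list(tangent = tan, n1 = n1, n2 = n2)
}

#' Generate a synthetic streamline bundle
#'
#' Streamlines are copies of the smooth centerline displaced radially: each
#' streamline draws one in-plane direction (uniform angle in the local
#' normal plane) and one signed Gaussian magnitude
#' (`sd = radial_dispersion_mm`), held constant along its length, plus small
#' independent per-point jitter. The expected distance from a streamline
#' point to the centerline is therefore `radial_dispersion_mm * sqrt(2/pi)`
#' (the mean of a half-normal), up to the jitter.
#'
#' @param spec A [bundle_spec()].
#' @return A [streamline_bundle()], bit-for-bit reproducible from the spec.
#' @export
make_bundle <- function(spec) {
  stopifnot(inherits(spec, "bundle_spec"))
  with_seed(spec$seed, {
    center <- spline_centerline(spec$centerline_control_points)
    center <- resample_polyline(center, spec$points_per_streamline)
    fr <- frame_along(center)
    streamlines <- lapply(seq_len(spec$n_streamlines), function(i) {
      phi <- stats::runif(1, 0, 2 * pi)
      mag <- stats::rnorm(1, 0, spec$radial_dispersion_mm)
      offset_dir <- cos(phi) * fr$n1 + sin(phi) * fr$n2
      jit <- matrix(stats::rnorm(3 * nrow(center), 0, spec$jitter_mm),
                    ncol = 3)
      center + mag * offset_dir + jit
    })
    streamline_bundle(streamlines, spec$name)
  })
}

# Per-voxel bundle occupancy: dominant fiber axis (principal eigenvector of
# the accumulated tangent outer products), mean along-tract arc fraction,
# and segment count, from the midpoints of all streamline segments.
bundle_voxel_stats <- function(bundle, grid) {
  dims <- grid$dim
  nvox <- prod(dims)
  occ_count <- numeric(nvox)
  arc_sum <- numeric(nvox)
  M <- matrix(0, nvox, 6)  # accumulated outer products (xx,xy,xz,yy,yz,zz)
  for (s in bundle$streamlines) {
    mids <- (s[-nrow(s), , drop = FALSE] + s[-1, , drop = FALSE]) / 2
    tans <- s[-1, , drop = FALSE] - s[-nrow(s), , drop = FALSE]
    tans <- tans / pmax(sqrt(rowSums(tans^2)), 1e-12)
    arc <- (seq_len(nrow(mids)) - 0.5) / nrow(mids)
    ijk <- round(world_to_voxel(grid$affine, mids))
    keep <- ijk[, 1] >= 0 & ijk[, 1] < dims[1] &
            ijk[, 2] >= 0 & ijk[, 2] < dims[2] &
            ijk[, 3] >= 0 & ijk[, 3] < dims[3]
    if (!any(keep)) next
    lin <- voxel_linear_index(dims, ijk[keep, , drop = FALSE])
    tk <- tans[keep, , drop = FALSE]
    op <- cbind(tk[, 1]^2, tk[, 1] * tk[, 2], tk[, 1] * tk[, 3],
                tk[, 2]^2, tk[, 2] * tk[, 3], tk[, 3]^2)
    acc <- rowsum(cbind(op, arc[keep]), lin)
    idx <- as.integer(rownames(acc))
    M[idx, ] <- M[idx, ] + acc[, 1:6, drop = FALSE]
    arc_sum[idx] <- arc_sum[idx] + acc[, 7]
    occ_count <- occ_count + tabulate(lin, nbins = nvox)
  }
  occupied <- which(occ_count > 0)
  axes <- matrix(0, length(occupied), 3)
  for (k in seq_along(occupied)) {
    v <- M[occupied[k], ]
    D <- matrix(c(v[1], v[2], v[3], v[2], v[4], v[5], v[3], v[5], v[6]), 3, 3)
    axes[k, ] <- eigen(D, symmetric = TRUE)$vectors[, 1]
  }
  list(occupied = occupied,
       axes = axes,
       arc_fraction = arc_sum[occupied] / occ_count[occupied],
       count = occ_count[occupied])
}

#' Generate an FOD coefficient field around a bundle
#'
#' In every voxel traversed by the bundle the FOD is an axially symmetric,
#' nonnegative lobe kernel `(d . u)^sh_order` aligned with the local
#' dominant fiber axis `u`, scaled so its analytic whole-sphere integral
#' equals the requested apparent fiber density; the kernel is a polynomial
#' of degree `sh_order` in the direction and is therefore represented
#' exactly in the even spherical-harmonic basis of that order. Voxels not
#' traversed are zero. An optional second crossing population splits the
#' integral between two axes.
#'
#' @param bundle A [streamline_bundle()].
#' @param baseline_afd Whole-sphere FOD integral in bundle voxels (may vary
#'   along the tract via `afd_profile`).
#' @param sh_order Even spherical-harmonic order (4, 6 or 8; default 8).
#' @param grid Voxel grid, as from [make_grid()]; default built from the
#'   bundle with 1.3 mm voxels.
#' @param crossing Optional `list(direction = unit axis, fraction = f)`
#'   adding a second population with integral `f * baseline`, the first
#'   keeping `1 - f`.
#' @param afd_profile Optional function of the along-tract arc fraction
#'   (0..1) returning the AFD for voxels at that position (overrides
#'   `baseline_afd` where occupied).
#' @param mesh Sphere mesh used to fit the kernel coefficients.
#' @return A [fod_field()].
#' @export
make_fod_field <- function(bundle, baseline_afd = 1, sh_order = 8L,
                           grid = NULL, crossing = NULL, afd_profile = NULL,
                           mesh = sphere_mesh(3L)) {
  if (!(sh_order %in% c(4L, 6L, 8L)))
    stop("sh_order must be one of 4, 6, 8")
  if (is.null(grid))
    grid <- make_grid(do.call(rbind, bundle$streamlines))
  n_sh <- sh_n_coef(sh_order)
  coefs <- array(0, c(grid$dim, n_sh))
  stats_ <- bundle_voxel_stats(bundle, grid)
  if (length(stats_$occupied) > 0 && any(baseline_afd != 0)) {
    afd <- if (is.null(afd_profile)) rep(baseline_afd, length(stats_$occupied))
           else afd_profile(stats_$arc_fraction)
    afd <- pmax(afd, 0)
    B <- sh_basis(mesh$vertices, sh_order)
    P <- solve(crossprod(B), t(B))      # projector onto the basis
    amp_scale <- (sh_order + 1) / (4 * pi)
    frac1 <- if (is.null(crossing)) 1 else 1 - crossing$fraction
    # amplitude samples for all occupied voxels at once (vertices x voxels)
    Famp <- amp_scale * (mesh$vertices %*% t(stats_$axes))^sh_order
    Fall <- sweep(Famp, 2, frac1 * afd, "*")
    if (!is.null(crossing)) {
      u2 <- crossing$direction / sqrt(sum(crossing$direction^2))
      f2 <- amp_scale * drop((mesh$vertices %*% u2))^sh_order
      Fall <- Fall + outer(f2, crossing$fraction * afd)
    }
    C <- P %*% Fall                     # n_sh x n_voxels
    nvox <- prod(grid$dim)
    for (j in seq_len(n_sh)) {
      slab <- numeric(nvox)
      slab[stats_$occupied] <- C[j, ]
      coefs[, , , j] <- array(slab, grid$dim)
    }
  }
  fod_field(coefs, grid$affine, sh_order)
}

# Axially symmetric tensor eigenvalues (a, b, b) with given FA and mean
# diffusivity. FA = (a - b) / sqrt(a^2 + 2 b^2) for a >= b >= 0.
tensor_eigs_from_fa <- function(fa, md) {
  if (fa <= 0) return(c(md, md, md))
  fa <- min(fa, 0.999)
  # solve (2 FA^2 - 1) k^2 + 2 k + (FA^2 - 1) = 0 for k = b/a in [0, 1]
  A <- 2 * fa^2 - 1; Bq <- 2; Cq <- fa^2 - 1
  if (abs(A) < 1e-12) {
    k <- -Cq / Bq
  } else {
    disc <- sqrt(Bq^2 - 4 * A * Cq)
    roots <- c((-Bq + disc) / (2 * A), (-Bq - disc) / (2 * A))
    k <- roots[roots >= 0 & roots <= 1][1]
  }
  a <- 3 * md / (1 + 2 * k)
  c(a, k * a, k * a)
}

#' Generate a diffusion-tensor field around a bundle
#'
#' Bundle voxels get an axially symmetric tensor aligned with the local
#' fiber axis at the requested fractional anisotropy and mean diffusivity;
#' other voxels are isotropic at the same mean diffusivity (FA = 0).
#'
#' @inheritParams make_fod_field
#' @param fa Target FA in bundle voxels (scalar, or varied via `fa_profile`).
#' @param md Mean diffusivity (default 0.7e-3 mm^2/s).
#' @param fa_profile Optional function of arc fraction returning FA.
#' @return A [tensor_field()].
#' @export
make_tensor_field <- function(bundle, fa = 0.6, md = 0.7e-3, grid = NULL,
                              fa_profile = NULL) {
  if (is.null(grid))
    grid <- make_grid(do.call(rbind, bundle$streamlines))
  dims <- grid$dim
  nvox <- prod(dims)
  tens <- matrix(0, nvox, 6)
  tens[, c(1, 4, 6)] <- md  # isotropic background
  stats_ <- bundle_voxel_stats(bundle, grid)
  if (length(stats_$occupied) > 0) {
    fav <- if (is.null(fa_profile)) rep(fa, length(stats_$occupied))
           else fa_profile(stats_$arc_fraction)
    fav <- pmin(pmax(fav, 0), 0.99)
    for (k in seq_along(stats_$occupied)) {
      ev <- tensor_eigs_from_fa(fav[k], md)
      u <- stats_$axes[k, ]
      D <- (ev[1] - ev[2]) * tcrossprod(u) + ev[2] * diag(3)
      tens[stats_$occupied[k], ] <- D[c(1, 2, 3, 5, 6, 9)]
    }
  }
  tensor_field(array(tens, c(dims, 6)), grid$affine)
}

#' Specification of a synthetic two-group cohort
#'
#' Defaults emulate a chronic-tinnitus case-control study: 19 subjects per
#' group; per-group confound distributions (hearing loss in dB, age in
#' years, tinnitus handicap inventory score, tinnitus duration in years)
#' with age and hearing loss jointly Gaussian at correlation 0.545; all
#' confounds truncated at 0 (negative draws rejected and redrawn). Controls
#' have THI = duration = 0. Group effects are injected into contiguous
#' along-tract segment windows as a shift of `delta * noise_sd` on the
#' metric baseline for group-2 (tinnitus) subjects.
#'
#' @param n_per_group Subjects per group (default 19).
#' @param confounds Per-group list of `c(mean, sd)` for `hl`, `age`, `thi`,
#'   `duration`.
#' @param age_hl_correlation Correlation between age and hearing loss within
#'   each group, in (-1, 1).
#' @param effect_windows List of `list(bundle =, metric =, start =, end =,
#'   delta =)`; `start`/`end` are 0-based segment indices in `[0, 100)`,
#'   inclusive; `delta` is the standardized effect size.
#' @param noise_sd Within-subject segmentwise metric noise sd (the paper-level
#'   noise model for subject variation is a package choice, kept as a knob).
#' @param seed RNG seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 19L,
                        confounds = list(
                          tinnitus = list(hl = c(20.2, 10.3),
                                          age = c(42.5, 11.6),
                                          thi = c(16.2, 10.5),
                                          duration = c(11.6, 7.6)),
                          control = list(hl = c(13.2, 3.8),
                                         age = c(42.5, 11.9),
                                         thi = c(0, 0),
                                         duration = c(0, 0))),
                        age_hl_correlation = 0.545,
                        effect_windows = list(),
                        noise_sd = 0.1, seed = 1L) {
  if (abs(age_hl_correlation) >= 1)
    stop("|age_hl_correlation| must be < 1")
  stopifnot(n_per_group >= 2, noise_sd > 0)
  for (w in effect_windows) {
    stopifnot(w$start >= 0, w$end < 100, w$start <= w$end,
              is.finite(w$delta))
  }
  structure(list(n_per_group = as.integer(n_per_group), confounds = confounds,
                 age_hl_correlation = age_hl_correlation,
                 effect_windows = effect_windows, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Draw one group's confounds: (age, HL) bivariate normal at the target
# correlation, THI and duration independent normals; any subject with a
# negative value is redrawn (truncation at 0).
sample_group_confounds <- function(n, params, rho) {
  draw_one <- function() {
    repeat {
      z1 <- stats::rnorm(1); z2 <- stats::rnorm(1)
      age <- params$age[1] + params$age[2] * z1
      hl <- params$hl[1] + params$hl[2] * (rho * z1 + sqrt(1 - rho^2) * z2)
      if (age >= 0 && hl >= 0) break
    }
    thi <- if (params$thi[2] == 0) params$thi[1] else {
      repeat { v <- stats::rnorm(1, params$thi[1], params$thi[2]); if (v >= 0) break }; v
    }
    dur <- if (params$duration[2] == 0) params$duration[1] else {
      repeat { v <- stats::rnorm(1, params$duration[1], params$duration[2]); if (v >= 0) break }; v
    }
    c(age = age, hl = hl, thi = thi, duration = dur)
  }
  t(vapply(seq_len(n), function(i) draw_one(), numeric(4)))
}

#' Sample the cohort table of a synthetic cohort
#'
#' @param cspec A [cohort_spec()].
#' @return Data frame with columns `subject`, `group` (control/tinnitus),
#'   `hl_db`, `thi`, `duration_y`, `age_y`; exactly `2 * n_per_group` rows.
#' @export
sample_cohort_table <- function(cspec) {
  with_seed(cspec$seed, {
    n <- cspec$n_per_group
    ctl <- sample_group_confounds(n, cspec$confounds$control,
                                  cspec$age_hl_correlation)
    tin <- sample_group_confounds(n, cspec$confounds$tinnitus,
                                  cspec$age_hl_correlation)
    data.frame(
      subject = c(sprintf("C%02d", seq_len(n)), sprintf("T%02d", seq_len(n))),
      group = rep(c("control", "tinnitus"), each = n),
      hl_db = c(ctl[, "hl"], tin[, "hl"]),
      thi = c(ctl[, "thi"], tin[, "thi"]),
      duration_y = c(ctl[, "duration"], tin[, "duration"]),
      age_y = c(ctl[, "age"], tin[, "age"]),
      stringsAsFactors = FALSE)
  })
}

# Deterministic smooth baseline profile for a named bundle: gentle
# along-tract variation so profiles are not flat, distinct per bundle.
baseline_profile <- function(bundle_name, n_segments = 100L, level = 1) {
  s <- (seq_len(n_segments) - 0.5) / n_segments
  ph <- (sum(utf8ToInt(bundle_name)) %% 7) / 7 * 2 * pi
  level * (1 + 0.15 * sin(2 * pi * s + ph) + 0.05 * cos(4 * pi * s + ph / 2))
}

#' Generate a two-group cohort at the profile level
#'
#' The fast path for statistical validation: per-subject along-tract
#' profiles are drawn directly at the metric level (smooth bundle baseline
#' + injected window effects for the tinnitus group + i.i.d. Gaussian
#' segment noise), skipping field synthesis and geometric profiling. With
#' no effect windows the two groups are exchangeable by construction, which
#' is what permutation-based error control is calibrated against.
#'
#' @param cspec A [cohort_spec()].
#' @param bundle_names Character vector of bundle labels.
#' @param n_segments Segments per bundle (default 100).
#' @param baseline_level Baseline metric level (default 1).
#' @return List with `cohort` (data frame, see [sample_cohort_table()]) and
#'   `profiles` (named list of subjects x segments [profile_matrix()]).
#' @export
make_profile_cohort <- function(cspec, bundle_names = c("bundleA", "bundleB",
                                                        "bundleC"),
                                n_segments = 100L, baseline_level = 1) {
  cohort <- sample_cohort_table(cspec)
  n_tot <- nrow(cohort)
  is_tin <- cohort$group == "tinnitus"
  profiles <- with_seed(cspec$seed + 1L, {
    out <- list()
    for (bn in bundle_names) {
      base <- baseline_profile(bn, n_segments, baseline_level)
      m <- matrix(stats::rnorm(n_tot * n_segments, 0, cspec$noise_sd),
                  n_tot, n_segments)
      m <- sweep(m, 2, base, "+")
      for (w in cspec$effect_windows) {
        if (!identical(w$bundle, bn)) next
        segs <- (w$start:w$end) + 1L
        m[is_tin, segs] <- m[is_tin, segs] + w$delta * cspec$noise_sd
      }
      out[[bn]] <- profile_matrix(asplit(m, 1), cohort$subject, bn,
                                  metric = "synthetic")
    }
    out
  })
  list(cohort = cohort, profiles = profiles)
}

#' Generate a full synthetic cohort with per-subject fields
#'
#' The integration-scale path: every subject gets regenerated bundle
#' geometry (subject-specific seed), an FOD field and a tensor field whose
#' along-tract baselines carry the subject's noise realization and — for
#' tinnitus subjects — the injected window effects. Intended for small
#' desk-scale configurations; statistical calibration uses
#' [make_profile_cohort()].
#'
#' @param cspec A [cohort_spec()].
#' @param bundle_specs List of [bundle_spec()]s.
#' @param baseline_afd Baseline whole-sphere FOD integral.
#' @param baseline_fa Baseline FA for the tensor fields.
#' @param voxel_size_mm Grid resolution (default 2.6 for desk scale).
#' @param sh_order FOD spherical-harmonic order.
#' @param fields Which voxel fields to generate (subset of "fod", "tensor").
#' @return List with `cohort` (data frame) and `subjects` (list of
#'   `subject_fields`: `subject_id`, `fod`, `tensor`, `bundle_set`).
#' @export
make_cohort <- function(cspec, bundle_specs, baseline_afd = 1,
                        baseline_fa = 0.6, voxel_size_mm = 2.6,
                        sh_order = 8L, fields = c("fod", "tensor")) {
  cohort <- sample_cohort_table(cspec)
  all_cp <- do.call(rbind, lapply(bundle_specs, `[[`,
                                  "centerline_control_points"))
  grid <- make_grid(all_cp, voxel_size_mm = voxel_size_mm,
                    margin_mm = 6 + 3 * max(vapply(bundle_specs, `[[`,
                                                   numeric(1),
                                                   "radial_dispersion_mm")))
  mesh <- sphere_mesh(3L)
  is_tin <- cohort$group == "tinnitus"
  subjects <- lapply(seq_len(nrow(cohort)), function(si) {
    sseed <- cspec$seed * 1000L + si
    bundle_set <- list()
    fod <- NULL; tens <- NULL
    for (bi in seq_along(bundle_specs)) {
      bs <- bundle_specs[[bi]]
      bss <- bs; bss$seed <- bs$seed + sseed
      b <- make_bundle(bss)
      bundle_set[[bs$name]] <- b
      # per-subject smooth baseline noise + window effects, per metric
      prof_for <- function(metric, level) {
        with_seed(sseed * 13L + bi * 7L + match(metric, c("afd", "fa")), {
          knots <- stats::rnorm(8, 0, cspec$noise_sd)
          function(s) {
            base <- level + stats::spline(seq(0, 1, length.out = 8), knots,
                                          xout = pmin(pmax(s, 0), 1))$y
            if (is_tin[si]) {
              for (w in cspec$effect_windows) {
                if (!identical(w$bundle, bs$name) ||
                    !identical(w$metric, metric)) next
                inwin <- s * 100 >= w$start & s * 100 < (w$end + 1)
                base[inwin] <- base[inwin] + w$delta * cspec$noise_sd
              }
            }
            base
          }
        })
      }
      if ("fod" %in% fields) {
        f <- make_fod_field(b, sh_order = sh_order, grid = grid,
                            afd_profile = prof_for("afd", baseline_afd),
                            mesh = mesh)
        if (is.null(fod)) fod <- f
        else fod$coefficients <- fod$coefficients + f$coefficients
      }
      if ("tensor" %in% fields) {
        tf <- make_tensor_field(b, md = 0.7e-3, grid = grid,
                                fa_profile = prof_for("fa", baseline_fa))
        if (is.null(tens)) tens <- tf
        else {
          # bundle voxels override the isotropic background of earlier fields
          occ <- rowSums(abs(matrix(tf$tensors, ncol = 6) -
                               matrix(rep(c(0.7e-3, 0, 0, 0.7e-3, 0, 0.7e-3),
                                          each = prod(grid$dim)),
                                      ncol = 6))) > 1e-12
          tmat <- matrix(tens$tensors, ncol = 6)
          tmat[occ, ] <- matrix(tf$tensors, ncol = 6)[occ, ]
          tens$tensors <- array(tmat, dim(tens$tensors))
        }
      }
    }
    list(subject_id = cohort$subject[si], fod = fod, tensor = tens,
         bundle_set = bundle_set)
  })
  list(cohort = cohort, subjects = subjects, grid = grid)
}
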