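#' Construct a streamline bundle
#'
#' @param streamlines List of n x 3 numeric matrices (ordered points, world
#'   mm); each must have at least 2 points and finite coordinates.
#' @param name Bundle label.
#' @return Object of class `streamline_bundle`.
#' @export
streamline_bundle <- function(streamlines, name = "bundle") {
  stopifnot(is.list(streamlines))
  streamlines <- lapply(streamlines, function(s) {
    s <- rbind(s)
    if (ncol(s) != 3 || nrow(s) < 2 || !all(is.finite(s)))
      stop("each streamline needs >= 2 finite 3D points")
    unname(s)
  })
  structure(list(name = name, streamlines = streamlines),
            class = "streamline_bundle")
}

#' @export
print.streamline_bundle <- function(x, ...) {
  np <- vapply(x$streamlines, nrow, integer(1))
  cat("streamline_bundle '", x$name, "': ", length(np),
      " streamlines, ", min(np), "-", max(np), " points each\n", sep = "")
  invisible(x)
}

#' Resample a polyline to equally spaced points by arc length
#'
#' @param polyline n x 3 matrix of ordered points.
#' @param n_points Number of output points (>= 2); endpoints are preserved.
#' @return `n_points` x 3 matrix.
#' @export
resample_polyline <- function(polyline, n_points) {
  polyline <- rbind(polyline)
  stopifnot(n_points >= 2, nrow(polyline) >= 2)
  seg <- diff(polyline)
  slen <- sqrt(rowSums(seg^2))
  s <- c(0, cumsum(slen))
  total <- s[length(s)]
  if (total <= 0) stop("zero-length polyline cannot be resampled")
  target <- seq(0, total, length.out = n_points)
  out <- matrix(0, n_points, 3)
  for (k in 1:3) out[, k] <- stats::approx(s, polyline[, k], xout = target,
                                           ties = "ordered")$y
  out
}

# Mean corresponding-point distance between two polylines already resampled
# to the same number of points; flip-invariant (min over direct and reversed
# ordering of b).
mdf_distance <- function(a, b) {
  direct <- mean(sqrt(rowSums((a - b)^2)))
  flipped <- mean(sqrt(rowSums((a - b[nrow(b):1, ])^2)))
  min(direct, flipped)
}

#' Centroid fiber of a bundle
#'
#' The along-tract coordinate system: every streamline is resampled to
#' `n_segments + 1` points, pairwise distances are the flip-invariant mean
#' corresponding-point (direct-flip) distances, and the centroid is the
#' member streamline minimizing the mean distance to all others (ties broken
#' by lowest streamline index). Its resampled polyline defines `n_segments`
#' segments indexed `0 .. n_segments - 1`.
#'
#' @param bundle A [streamline_bundle()] with >= 1 streamline.
#' @param n_segments Number of along-tract segments (default 100).
#' @return Object of class `centroid_profile`: list with `bundle_name`,
#'   `points` ((n_segments + 1) x 3), `n_segments`, `index` (which member
#'   streamline won).
#' @export
bundle_centroid <- function(bundle, n_segments = 100L) {
  stopifnot(inherits(bundle, "streamline_bundle"), n_segments >= 1)
  n <- length(bundle$streamlines)
  if (n == 0) stop("empty bundle has no centroid")
  rs <- lapply(bundle$streamlines, resample_polyline, n_points = n_segments + 1L)
  if (n == 1) {
    idx <- 1L
  } else {
    D <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- mdf_distance(rs[[i]], rs[[j]])
    }
    idx <- which.min(rowSums(D) / (n - 1))  # which.min takes lowest index on ties
  }
  structure(list(bundle_name = bundle$name, points = rs[[idx]],
                 n_segments = as.integer(n_segments), index = idx),
            class = "centroid_profile")
}

#' @export
print.centroid_profile <- function(x, ...) {
  cat("centroid_profile '", x$bundle_name, "': ", x$n_segments,
      " segments (member streamline ", x$index, ")\n", sep = "")
  invisible(x)
}

#' Orient all streamlines consistently with the centroid
#'
#' Flips each streamline (reverses its stored point order) whenever the
#' flipped corresponding-point distance to the centroid is smaller than the
#' direct one, so that "beginning" and "end" agree across the bundle.
#' Idempotent; never increases any streamline's distance to the centroid.
#'
#' @param bundle A [streamline_bundle()].
#' @param centroid A [bundle_centroid()] of (usually) the same bundle.
#' @return The reoriented [streamline_bundle()].
#' @export
orient_bundle <- function(bundle, centroid) {
  np <- centroid$n_segments + 1L
  cpts <- centroid$points
  flipped <- lapply(bundle$streamlines, function(s) {
    r <- resample_polyline(s, np)
    direct <- mean(sqrt(rowSums((r - cpts)^2)))
    rev_d <- mean(sqrt(rowSums((r[np:1, ] - cpts)^2)))
    if (rev_d < direct) s[nrow(s):1, , drop = FALSE] else s
  })
  streamline_bundle(flipped, bundle$name)
}

#' Assign streamline segments to centroid segments
#'
#' Every streamline is resampled to `n_segments + 1` points (yielding
#' `n_segments` small segments); each small segment's midpoint is assigned
#' the index (0-based) of the centroid segment whose midpoint is nearest in
#' Euclidean distance.
#'
#' @param bundle An oriented [streamline_bundle()].
#' @param centroid A [bundle_centroid()].
#' @return List with one integer vector (length `n_segments`, values in
#'   `0 .. n_segments - 1`) per streamline, plus attributes `midpoints` and
#'   `tangents` (lists of per-streamline n_segments x 3 matrices) used by
#'   [tract_profile()].
#' @export
assign_segments <- function(bundle, centroid) {
  ns <- centroid$n_segments
  cmid <- (centroid$points[-(ns + 1), , drop = FALSE] +
             centroid$points[-1, , drop = FALSE]) / 2
  mids <- list(); tans <- list()
  assignments <- lapply(seq_along(bundle$streamlines), function(i) {
    r <- resample_polyline(bundle$streamlines[[i]], ns + 1L)
    mid <- (r[-(ns + 1), , drop = FALSE] + r[-1, , drop = FALSE]) / 2
    tan <- r[-1, , drop = FALSE] - r[-(ns + 1), , drop = FALSE]
    tan <- tan / pmax(sqrt(rowSums(tan^2)), 1e-12)
    mids[[i]] <<- mid; tans[[i]] <<- tan
    # nearest centroid-segment midpoint for every streamline-segment midpoint
    d2 <- outer(rowSums(mid^2), rowSums(cmid^2), "+") - 2 * mid %*% t(cmid)
    max.col(-d2, ties.method = "first") - 1L
  })
  attr(assignments, "midpoints") <- mids
  attr(assignments, "tangents") <- tans
  assignments
}

#' Along-tract profile of one subject for one metric
#'
#' Samples the metric at the midpoint of every small streamline segment
#' (with the local streamline tangent as the reference axis for the
#' direction-dependent metrics) and averages the sampled values per assigned
#' centroid segment. Segments to which no streamline segment was assigned,
#' or whose every sample fell outside the field, are `NA` (missing, never
#' imputed); more than 20% missing raises a warning, all missing is an
#' error.
#'
#' @param bundle A [streamline_bundle()] (will be oriented internally).
#' @param centroid A [bundle_centroid()].
#' @param field A [fod_field()] (for `"afd"` / `"peak"`) or
#'   [tensor_field()] (for `"fa"`).
#' @param metric One of `"afd"`, `"peak"`, `"fa"`.
#' @param mesh Sphere mesh for the FOD metrics.
#' @param amplitude_floor_frac Lobe floor, see [segment_lobes()].
#' @return Numeric vector of length `centroid$n_segments` (one value per
#'   along-tract position, `NA` = missing).
#' @export
tract_profile <- function(bundle, centroid, field,
                          metric = c("afd", "peak", "fa"),
                          mesh = sphere_mesh(3L),
                          amplitude_floor_frac = 0.1) {
  metric <- match.arg(metric)
  bundle <- orient_bundle(bundle, centroid)
  asg <- assign_segments(bundle, centroid)
  mids <- do.call(rbind, attr(asg, "midpoints"))
  tans <- do.call(rbind, attr(asg, "tangents"))
  idx <- unlist(asg)
  vals <- sample_metric(field, mids, tans, metric, mesh, amplitude_floor_frac)
  ns <- centroid$n_segments
  keep <- !is.na(vals)
  sums <- rep(0, ns); counts <- rep(0L, ns)
  if (any(keep)) {
    tb <- tapply(vals[keep], factor(idx[keep], levels = 0:(ns - 1)), mean)
    prof <- as.numeric(tb)
  } else {
    prof <- rep(NA_real_, ns)
  }
  n_missing <- sum(is.na(prof))
  if (n_missing == ns) stop("all along-tract segments are missing")
  if (n_missing > 0.2 * ns)
    warning(sprintf("%d of %d along-tract segments have no assigned points",
                    n_missing, ns))
  prof
}

# Vectorized metric sampling at many midpoints; NA where out of bounds.
sample_metric <- function(field, points, tangents, metric, mesh,
                          amplitude_floor_frac) {
  n <- nrow(points)
  out <- rep(NA_real_, n)
  if (metric == "fa") {
    for (i in seq_len(n)) {
      out[i] <- tryCatch(fa_at(field, points[i, ]), error = function(e) NA_real_)
    }
    return(out)
  }
  stopifnot(inherits(field, "fod_field"))
  coefs <- tryCatch(fod_coefficients_at(field, points), error = function(e) NULL)
  if (is.null(coefs)) {
    # some points out of bounds: fall back to per-point interpolation
    coefs <- matrix(NA_real_, n, dim(field$coefficients)[4])
    for (i in seq_len(n)) {
      ci <- tryCatch(drop(interp_field(field$coefficients, field$affine,
                                       points[i, , drop = FALSE])),
                     error = function(e) NULL)
      if (!is.null(ci)) coefs[i, ] <- ci
    }
  }
  B <- sh_basis(mesh$vertices, field$sh_order)
  amps <- coefs %*% t(B)            # n x n_vertices
  amps[amps < 0] <- 0
  for (i in seq_len(n)) {
    a <- amps[i, ]
    if (anyNA(a)) next
    lobes <- lobes_from_amplitudes(a, mesh, amplitude_floor_frac)
    lobe <- select_lobe(lobes, tangents[i, ])
    if (is.null(lobe)) { out[i] <- 0; next }
    out[i] <- if (metric == "afd") lobe$integral else lobe$peak_amplitude
  }
  out
}

#' Stack subject profiles into a profile matrix
#'
#' @param rows List of per-subject profile vectors (equal length).
#' @param subject_ids Character vector of subject labels.
#' @param bundle_name,metric Labels recorded as attributes.
#' @return Numeric matrix subjects x segments with attributes `bundle_name`,
#'   `metric`, and rownames = subject ids; class `profile_matrix`.
#' @export
profile_matrix <- function(rows, subject_ids, bundle_name, metric) {
  m <- do.call(rbind, rows)
  rownames(m) <- subject_ids
  colnames(m) <- sprintf("seg%03d", seq_len(ncol(m)) - 1L)
  structure(m, bundle_name = bundle_name, metric = metric,
            class = c("profile_matrix", "matrix", "array"))
}

#' Z-normalize a profile matrix within its bundle
#'
#' Subtracts the bundle-wise mean and divides by the bundle-wise standard
#' deviation, both computed over all subjects and segments of the matrix
#' (missing values excluded). Used to overlay metrics with different units
#' on one axis. A constant matrix (sd = 0) returns all zeros with attribute
#' `degenerate = TRUE`.
#'
#' @param m Profile matrix (subjects x segments).
#' @return Matrix of the same shape.
#' @export
znorm_profiles <- function(m) {
  mu <- mean(m, na.rm = TRUE)
  sdev <- stats::sd(as.numeric(m), na.rm = TRUE)
  if (!is.finite(sdev) || sdev == 0) {
    out <- m; out[] <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- (m - mu) / sdev
  attr(out, "degenerate") <- FALSE
  out
}
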