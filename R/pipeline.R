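#' Tract-profile plot for one bundle and metric
#'
#' Group mean with a +/- 1 sd ribbon per group versus along-tract segment,
#' with FWE-significant regions (surviving clusters, if provided) shaded.
#'
#' @param m Subjects x segments [profile_matrix()].
#' @param groups Two-level factor of subjects.
#' @param clusters Optional cluster table from [cluster_filter()] (only the
#'   rows of this bundle are used).
#' @param title Plot title; defaults to bundle/metric attributes.
#' @return A ggplot object.
#' @export
plot_tract_profile <- function(m, groups, clusters = NULL, title = NULL) {
  groups <- as.factor(groups)
  ns <- ncol(m)
  df <- do.call(rbind, lapply(levels(groups), function(g) {
    sub <- m[groups == g, , drop = FALSE]
    data.frame(segment = seq_len(ns) - 1L, group = g,
               mean = colMeans(sub, na.rm = TRUE),
               sd = apply(sub, 2, stats::sd, na.rm = TRUE))
  }))
  if (is.null(title))
    title <- paste(attr(m, "bundle_name"), attr(m, "metric"), sep = " - ")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$segment, y = .data$mean,
                                        colour = .data$group,
                                        fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "along-tract segment", y = attr(m, "metric"),
                  title = title) +
    ggplot2::theme_minimal()
  if (!is.null(clusters) && nrow(clusters) > 0) {
    cl <- clusters[clusters$bundle == attr(m, "bundle_name"), , drop = FALSE]
    if (nrow(cl) > 0)
      p <- p + ggplot2::annotate("rect", xmin = cl$start - 0.5,
                                 xmax = cl$end + 0.5, ymin = -Inf, ymax = Inf,
                                 alpha = 0.15, fill = "grey20")
  }
  p
}

#' Z-normalized multi-metric comparison plot
#'
#' Overlays the group-mean difference profiles of several metrics for one
#' bundle after z-transforming each metric within the bundle, so metrics
#' with different units share one axis.
#'
#' @param m_list Named list of [profile_matrix()] (one per metric, same
#'   bundle and subjects).
#' @param groups Two-level factor.
#' @return A ggplot object.
#' @export
plot_znorm_comparison <- function(m_list, groups) {
  groups <- as.factor(groups)
  lv <- levels(groups)
  df <- do.call(rbind, lapply(names(m_list), function(nm) {
    z <- znorm_profiles(m_list[[nm]])
    diffm <- colMeans(z[groups == lv[2], , drop = FALSE], na.rm = TRUE) -
      colMeans(z[groups == lv[1], , drop = FALSE], na.rm = TRUE)
    data.frame(segment = seq_len(ncol(z)) - 1L, metric = nm, diff = diffm)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$segment, y = .data$diff,
                                   colour = .data$metric)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "along-tract segment",
                  y = sprintf("z-scored %s - %s difference", lv[2], lv[1])) +
    ggplot2::theme_minimal()
}

#' Load a pipeline run configuration
#'
#' YAML file with optional blocks `bundles` (list of [bundle_spec()]
#' fields), `cohort` ([cohort_spec()] fields), `stats` ([stats_config()]
#' fields), `metrics` (subset of afd/peak/fa) and `seed`. Unknown keys are
#' an error so typos do not silently change a run.
#'
#' @param path YAML file.
#' @return Validated config list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  known <- c("bundles", "cohort", "stats", "metrics", "seed", "out_dir")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg$metrics <- if (is.null(cfg$metrics)) c("afd", "peak", "fa")
                 else match.arg(cfg$metrics, c("afd", "peak", "fa"),
                                several.ok = TRUE)
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg
}

default_bundle_specs <- function(seed = 1L, n_streamlines = 60L,
                                 points_per_streamline = 40L) {
  list(
    bundle_spec("arcuate_like",
                rbind(c(0, 0, 0), c(20, 8, 4), c(40, 10, 14), c(55, 2, 22)),
                n_streamlines = n_streamlines, radial_dispersion_mm = 1.5,
                points_per_streamline = points_per_streamline, seed = seed),
    bundle_spec("uncinate_like",
                rbind(c(0, 30, 0), c(15, 38, 6), c(32, 33, 14), c(44, 24, 10)),
                n_streamlines = n_streamlines, radial_dispersion_mm = 1.5,
                points_per_streamline = points_per_streamline, seed = seed + 1L),
    bundle_spec("cst_like",
                rbind(c(25, 60, -10), c(26, 62, 8), c(30, 66, 26),
                      c(38, 70, 40)),
                n_streamlines = n_streamlines, radial_dispersion_mm = 1.5,
                points_per_streamline = points_per_streamline, seed = seed + 2L))
}

#' Run the full simulate -> profile -> stats -> report pipeline
#'
#' Generates (or reuses) a synthetic cohort with per-subject FOD/tensor
#' fields and bundles, computes per-subject 100-segment profiles for the
#' requested metrics, runs the confound-adjusted permutation group
#' comparison per metric, and writes cohort TSV, per-bundle profile TSVs,
#' per-metric segment/cluster stat TSVs and tract-profile figures into
#' `out_dir`. Deterministic for a fixed seed.
#'
#' @param out_dir Output directory (created if needed).
#' @param bundle_specs List of [bundle_spec()]s (default: three small
#'   desk-scale bundles).
#' @param cspec A [cohort_spec()].
#' @param cfg A [stats_config()].
#' @param metrics Metrics to profile, subset of `c("afd", "peak", "fa")`.
#' @param n_segments Along-tract segments (default 100).
#' @param voxel_size_mm Synthetic grid resolution.
#' @param sphere_subdivisions Mesh level for the FOD metrics (default 2 at
#'   desk scale; use 3+ for production accuracy).
#' @param write_figures Write PNG tract-profile figures (default TRUE).
#' @return Invisibly, a list with `cohort`, `profiles` (metric -> bundle ->
#'   matrix), `results` (metric -> [group_comparison()] output), `out_dir`.
#' @export
run_pipeline <- function(out_dir, bundle_specs = NULL,
                         cspec = cohort_spec(n_per_group = 5L, seed = 7L),
                         cfg = stats_config(n_permutations = 500L, seed = 7L),
                         metrics = c("afd", "fa"), n_segments = 100L,
                         voxel_size_mm = 2.6, sphere_subdivisions = 2L,
                         write_figures = TRUE) {
  metrics <- match.arg(metrics, c("afd", "peak", "fa"), several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(bundle_specs))
    bundle_specs <- default_bundle_specs(seed = cspec$seed)
  need_fod <- any(c("afd", "peak") %in% metrics)
  need_tensor <- "fa" %in% metrics
  fields <- c(if (need_fod) "fod", if (need_tensor) "tensor")

  sim <- make_cohort(cspec, bundle_specs, fields = fields,
                     voxel_size_mm = voxel_size_mm)
  write_cohort_tsv(sim$cohort, file.path(out_dir, "cohort.tsv"))
  mesh <- sphere_mesh(sphere_subdivisions)

  # centroid per bundle from the first subject's geometry (the along-tract
  # coordinate system must be shared across subjects)
  centroids <- lapply(sim$subjects[[1]]$bundle_set, bundle_centroid,
                      n_segments = n_segments)

  profiles <- list()
  for (metric in metrics) {
    per_bundle <- list()
    for (bn in names(centroids)) {
      rows <- lapply(sim$subjects, function(subj) {
        field <- if (metric == "fa") subj$tensor else subj$fod
        tract_profile(subj$bundle_set[[bn]], centroids[[bn]], field,
                      metric = metric, mesh = mesh)
      })
      pm <- profile_matrix(rows, sim$cohort$subject, bn, metric)
      per_bundle[[bn]] <- pm
      write_profile_tsv(pm, file.path(out_dir,
                                      sprintf("profile_%s_%s.tsv", bn, metric)))
    }
    profiles[[metric]] <- per_bundle
  }

  results <- list()
  for (metric in metrics) {
    res <- group_comparison(profiles[[metric]], sim$cohort, cfg)
    results[[metric]] <- res
    utils::write.table(res$segments,
                       file.path(out_dir, sprintf("segments_%s.tsv", metric)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$clusters,
                       file.path(out_dir, sprintf("clusters_%s.tsv", metric)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (write_figures) {
      for (bn in names(profiles[[metric]])) {
        p <- plot_tract_profile(profiles[[metric]][[bn]], sim$cohort$group,
                                res$clusters)
        ggplot2::ggsave(file.path(out_dir,
                                  sprintf("profile_%s_%s.png", bn, metric)),
                        p, width = 7, height = 4, dpi = 110)
      }
    }
  }
  if (write_figures && length(metrics) > 1) {
    bn1 <- names(profiles[[metrics[1]]])[1]
    p <- plot_znorm_comparison(lapply(profiles, `[[`, bn1), sim$cohort$group)
    ggplot2::ggsave(file.path(out_dir, sprintf("znorm_%s.png", bn1)),
                    p, width = 7, height = 4, dpi = 110)
  }
  invisible(list(cohort = sim$cohort, profiles = profiles, results = results,
                 out_dir = out_dir))
}
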