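#' Analysis configuration
#'
#' Bundles every tunable of the study pipeline with the defaults used
#' throughout: D(s) evaluated up to 8 km; scan windows capped at 5 km;
#' 999 relabelings for the D(s) envelope; 9999 Monte Carlo replications for
#' the scan p-value; significance level 0.05; Ripley's isotropic edge
#' correction; 6 matched controls per case.
#'
#' @param s_max_dstat maximum distance for D(s), meters.
#' @param max_radius_scan maximum scan-window radius, meters.
#' @param n_sim_dstat relabelings for the envelope.
#' @param n_replications_scan Monte Carlo replications for the scan.
#' @param alpha significance level.
#' @param correction edge correction, \code{"isotropic"} or \code{"none"}.
#' @param matching_ratio controls per case.
#' @param seed integer master seed; per-group seeds are derived from it.
#' @param group_by grouping column names for multi-group datasets.
#' @export
analysis_config <- function(s_max_dstat = 8000, max_radius_scan = 5000,
                            n_sim_dstat = 999, n_replications_scan = 9999,
                            alpha = 0.05,
                            correction = c("isotropic", "none"),
                            matching_ratio = 6, seed = NULL,
                            group_by = c("cause", "region_group")) {
  stopifnot(s_max_dstat > 0, max_radius_scan > 0, n_sim_dstat >= 19,
            n_replications_scan >= 0, alpha > 0, alpha < 1,
            matching_ratio >= 1)
  correction <- match.arg(correction)
  structure(list(s_max_dstat = s_max_dstat, max_radius_scan = max_radius_scan,
                 n_sim_dstat = as.integer(n_sim_dstat),
                 n_replications_scan = as.integer(n_replications_scan),
                 alpha = alpha, correction = correction,
                 matching_ratio = as.integer(matching_ratio), seed = seed,
                 group_by = group_by), class = "analysis_config")
}

#' Run the full per-group clustering and cluster-detection study
#'
#' For every (cause, region-group) dataset: the difference-of-K clustering
#' test with its random-labeling envelope, and the Bernoulli spatial scan.
#' Region groups are always analysed independently, never pooled. Groups
#' with fewer than 2 cases or 2 controls are skipped with a warning.
#'
#' @param dataset a \code{\link{cc_pattern}} or a named list of them (as
#'   returned by \code{\link{read_dataset}}).
#' @param config an \code{\link{analysis_config}}.
#' @return an object of class \code{"cc_study"}: list with \code{groups}
#'   (per group: \code{envelope}, \code{scan}, \code{seed}), \code{summary}
#'   (one row per group mirroring the published cluster table: counts,
#'   at-risk inside the most likely cluster, cases inside, expected cases to
#'   2 decimals, p-value to 3 decimals, radius in whole meters, centre
#'   coordinates) and \code{config}.
#' @export
run_study <- function(dataset, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  if (inherits(dataset, "cc_pattern")) dataset <- list(all = dataset)
  stopifnot(length(dataset) >= 1)
  groups <- list()
  rows <- list()
  for (i in seq_along(dataset)) {
    nm <- names(dataset)[i]
    d <- dataset[[i]]
    if (d$n_cases < 2 || d$n_controls < 2) {
      warning("group '", nm, "' has fewer than 2 cases or 2 controls; skipped")
      next
    }
    gseed <- if (!is.null(config$seed))
      (as.integer(config$seed) + 101L * i) %% .Machine$integer.max else NULL
    env <- random_labeling_envelope(d, n_sim = config$n_sim_dstat,
                                    correction = config$correction,
                                    s_max = config$s_max_dstat, seed = gseed)
    sc <- scan_bernoulli(d, max_radius = config$max_radius_scan,
                         n_replications = config$n_replications_scan,
                         alpha = config$alpha,
                         seed = if (is.null(gseed)) NULL else gseed + 1L)
    groups[[nm]] <- list(envelope = env, scan = sc, seed = gseed)
    p <- sc$primary
    rows[[nm]] <- data.frame(
      group = nm,
      n_cases = d$n_cases, n_controls = d$n_controls,
      atrisk_inside = if (is.null(p)) NA_integer_ else p$atrisk_inside,
      cases_inside = if (is.null(p)) NA_integer_ else p$n_inside,
      expected_cases = if (is.null(p)) NA_real_ else round(p$expected_cases, 2),
      p_value = if (is.null(p)) NA_real_ else round(p$p_value, 3),
      radius_m = if (is.null(p)) NA_integer_ else as.integer(round(p$radius)),
      center_x = if (is.null(p)) NA_real_ else p$center_x,
      center_y = if (is.null(p)) NA_real_ else p$center_y,
      d_exceeds_upper = sum(env$exceed_upper),
      d_exceeds_lower = sum(env$exceed_lower))
  }
  if (!length(groups)) stop("no analysable group in the dataset")
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  structure(list(groups = groups, summary = summary, config = config),
            class = "cc_study")
}

#' @export
print.cc_study <- function(x, ...) {
  cat("case-control spatial study:", length(x$groups), "group(s)\n")
  print(x$summary)
  invisible(x)
}

#' Write a study report bundle to disk
#'
#' Writes the summary table, per-group D(s) envelope tables (distance,
#' observed D, envelope limits, verdict), the reported clusters, a JSON run
#' log (configuration, per-group seeds) and optional per-group plots.
#'
#' @param study a \code{"cc_study"}.
#' @param dir output directory (created if missing).
#' @param plots also write PNG figures per group.
#' @param datasets optional named list of the analysed \code{cc_pattern}s,
#'   needed for the scan plots.
#' @return \code{dir}, invisibly.
#' @export
write_study_report <- function(study, dir, plots = FALSE, datasets = NULL) {
  stopifnot(inherits(study, "cc_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(study$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE, quote = FALSE)
  clus <- list()
  for (nm in names(study$groups)) {
    g <- study$groups[[nm]]
    env <- g$envelope
    utils::write.csv(
      data.frame(s = env$s_grid, d = env$d_values,
                 lower = env$lower_envelope, upper = env$upper_envelope,
                 verdict = as.character(interpret(env))),
      file.path(dir, paste0("dstat_", gsub("[^A-Za-z0-9_.-]", "_", nm), ".csv")),
      row.names = FALSE, quote = FALSE)
    if (nrow(g$scan$ranked))
      clus[[nm]] <- cbind(group = nm, g$scan$ranked)
    if (plots) {
      f <- file.path(dir, paste0("dstat_", gsub("[^A-Za-z0-9_.-]", "_", nm), ".png"))
      grDevices::png(f, 900, 600)
      plot(env, main = nm)
      grDevices::dev.off()
      if (!is.null(datasets[[nm]])) {
        f <- file.path(dir, paste0("scan_", gsub("[^A-Za-z0-9_.-]", "_", nm), ".png"))
        grDevices::png(f, 900, 900)
        plot(g$scan, datasets[[nm]], main = nm)
        grDevices::dev.off()
      }
    }
  }
  if (length(clus))
    utils::write.csv(do.call(rbind, clus), file.path(dir, "clusters.csv"),
                     row.names = FALSE, quote = FALSE)
  log <- list(config = unclass(study$config),
              group_seeds = lapply(study$groups, function(g) g$seed),
              timestamp_note = "seeds fully determine the Monte Carlo output")
  jsonlite::write_json(log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
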