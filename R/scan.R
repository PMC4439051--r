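#' Bernoulli scan likelihood kernel
#'
#' Log likelihood-ratio kernel for a circular window under the Bernoulli
#' (case-control) model. With \eqn{n_i} cases among \eqn{N_i} at-risk
#' individuals inside the window and \eqn{m_i} cases among \eqn{M_i} at risk
#' outside, the default kernel is
#' \deqn{\log LR_i = n_i \log(n_i/N_i) + m_i \log(m_i/M_i)}
#' evaluated only where the risk inside exceeds the risk outside
#' (\eqn{n_i/N_i > m_i/M_i}); windows failing that indicator are not cluster
#' candidates and return \code{-Inf}. \code{kernel = "bernoulli"} instead
#' returns the full Bernoulli log likelihood ratio of the scan-statistic
#' literature (adding the \eqn{(N_i-n_i)} and \eqn{(M_i-m_i)} terms and
#' subtracting the null log likelihood); the two rank windows very similarly
#' and share the candidate indicator. The convention \eqn{0\log 0 = 0}
#' applies.
#'
#' @param n_in cases inside the window (\eqn{n_i}).
#' @param N_in at-risk individuals (cases + controls) inside (\eqn{N_i}).
#' @param n_out cases outside (\eqn{m_i}).
#' @param M_out at-risk individuals outside (\eqn{M_i}).
#' @param kernel \code{"ratio"} (default, the kernel above) or
#'   \code{"bernoulli"}.
#' @return log kernel value, or \code{-Inf} for non-candidate windows.
#' @examples
#' log_lr_kernel(5, 5, 633, 4461)
#' log_lr_kernel(1, 2, 2, 4)  # equal risk: -Inf, not a candidate
#' @export
log_lr_kernel <- function(n_in, N_in, n_out, M_out,
                          kernel = c("ratio", "bernoulli")) {
  kernel <- match.arg(kernel)
  stopifnot(n_in >= 0, n_out >= 0, N_in >= n_in, M_out >= n_out)
  if (N_in == 0) stop("window contains no at-risk individuals")
  llr_counts_cpp(n_in, N_in, n_out, M_out, match(kernel, c("ratio", "bernoulli")) - 1L)
}

#' Expected cases in a window
#'
#' Under spatially constant risk, the expected number of cases in a window
#' holding \code{N_in} of the \code{N_total} at-risk individuals is
#' \deqn{E_i = C \cdot N_i / N_{total}.}
#'
#' @param C total cases in the study group.
#' @param N_in at-risk individuals inside the window.
#' @param N_total at-risk individuals in the whole study group.
#' @examples
#' expected_cases(638, 5, 4466)  # 0.714 -> printed 0.7
#' @export
expected_cases <- function(C, N_in, N_total) {
  stopifnot(C >= 0, N_in >= 0, N_total >= N_in)
  if (N_total == 0) stop("no at-risk individuals")
  C * N_in / N_total
}

#' Enumerate candidate scan windows
#'
#' For each case location, the scanning disc grows from radius zero to
#' \code{max_radius}; the distinct windows are indexed by the sorted distances
#' from the centre to every at-risk point within reach (closed discs, so all
#' points at the boundary distance enter together). Intended for small
#' problems and oracle checks; \code{\link{scan_bernoulli}} walks the same
#' windows without materialising them.
#'
#' @param data a \code{cc_pattern}.
#' @param max_radius maximum window radius (meters).
#' @return data frame with one row per candidate window: \code{center}
#'   (point index), \code{radius}, and a list column \code{members} of point
#'   indices inside.
#' @export
enumerate_windows <- function(data, max_radius = 5000) {
  stopifnot(inherits(data, "cc_pattern"), data$n_cases >= 1)
  centers <- which(data$label == "case")
  out <- lapply(centers, function(c0) {
    d <- sqrt((data$x - data$x[c0])^2 + (data$y - data$y[c0])^2)
    radii <- sort(unique(d[d <= max_radius]))
    data.frame(center = c0, radius = radii,
               members = I(lapply(radii, function(r) which(d <= r))))
  })
  do.call(rbind, out)
}

#' Purely spatial Bernoulli scan statistic
#'
#' Kulldorff's scan for case-control point data: circular windows centred at
#' case addresses, radius growing from zero to \code{max_radius}, each window
#' scored by the Bernoulli likelihood-ratio kernel
#' (\code{\link{log_lr_kernel}}). The most likely cluster is the window
#' maximising the kernel; its p-value comes from Monte Carlo hypothesis
#' testing under the constant-risk null, re-drawing the case labels uniformly
#' over all at-risk locations (holding the number of cases fixed) and
#' recomputing the maximum for each replicate:
#' \code{p = (1 + #\{T_rep >= T_obs\}) / (n_replications + 1)}.
#'
#' Reported clusters are the best window per centre, ranked by descending
#' log-likelihood ratio (ties broken by smaller radius, then lower centre
#' index) after removing windows whose disc geometrically overlaps a
#' higher-ranked reported cluster.
#'
#' @param data a \code{cc_pattern} with at least 1 case and 1 control.
#' @param max_radius maximum window radius in meters; default 5000.
#' @param n_replications Monte Carlo replicates for p-values; default 9999.
#'   Use 0 to skip the Monte Carlo stage (p-values \code{NA}).
#' @param alpha significance level recorded in the result; default 0.05.
#' @param kernel likelihood kernel, as in \code{\link{log_lr_kernel}}.
#' @param centers \code{"cases"} (default) to centre windows at case
#'   addresses only, or \code{"all"} to centre at every at-risk location.
#' @param max_reported cap on the number of non-overlapping clusters reported.
#' @param seed optional integer seed.
#' @return an object of class \code{"scan_result"}: list with
#'   \code{total_cases}, \code{total_atrisk}, \code{primary} (a one-row
#'   cluster data frame), \code{ranked} (data frame of reported clusters with
#'   \code{center_x}, \code{center_y}, \code{radius}, \code{n_inside},
#'   \code{atrisk_inside}, \code{n_outside}, \code{atrisk_outside},
#'   \code{log_lr}, \code{expected_cases}, \code{p_value}),
#'   \code{member_indices} (list, per reported cluster), \code{t_obs},
#'   \code{t_null}, and the call parameters.
#' @export
scan_bernoulli <- function(data, max_radius = 5000, n_replications = 9999,
                           alpha = 0.05, kernel = c("ratio", "bernoulli"),
                           centers = c("cases", "all"), max_reported = 10,
                           seed = NULL) {
  stopifnot(inherits(data, "cc_pattern"))
  kernel <- match.arg(kernel)
  centers <- match.arg(centers)
  if (data$n_cases < 1 || data$n_controls < 1)
    stop("need at least 1 case and 1 control")
  if (!is.null(seed)) set.seed(seed)
  kern <- match(kernel, c("ratio", "bernoulli")) - 1L

  prep <- scan_prep_cpp(data$x, data$y, max_radius)
  is_case <- as.integer(data$label == "case")
  obs <- scan_observed_cpp(prep$offsets, prep$idx, prep$dist, is_case, kern)
  if (centers == "all") {
    # also centre windows at control addresses (scored with the true labels)
    obs <- rbind(obs, rescore_centers(data, which(is_case == 0L), max_radius, kern))
  }
  obs <- obs[is.finite(obs$llr), , drop = FALSE]

  t_null <- if (n_replications > 0)
    scan_null_cpp(prep$offsets, prep$idx, prep$dist, data$n, data$n_cases,
                  kern, n_replications) else numeric(0)

  if (nrow(obs) == 0) {
    res <- structure(list(total_cases = data$n_cases,
                          total_atrisk = data$n,
                          primary = NULL,
                          ranked = empty_cluster_df(),
                          member_indices = list(),
                          t_obs = -Inf, t_null = t_null,
                          n_replications = n_replications,
                          max_radius = max_radius, alpha = alpha,
                          kernel = kernel, seed = seed),
                     class = "scan_result")
    return(res)
  }

  ord <- order(-obs$llr, obs$radius, obs$center)
  obs <- obs[ord, , drop = FALSE]
  keep <- integer(0)
  for (i in seq_len(nrow(obs))) {
    ok <- TRUE
    for (j in keep) {
      dc <- sqrt((data$x[obs$center[i]] - data$x[obs$center[j]])^2 +
                 (data$y[obs$center[i]] - data$y[obs$center[j]])^2)
      if (dc < obs$radius[i] + obs$radius[j]) { ok <- FALSE; break }
    }
    if (ok) keep <- c(keep, i)
    if (length(keep) >= max_reported) break
  }
  rep_df <- obs[keep, , drop = FALSE]

  pval <- function(t) if (n_replications > 0)
    (1 + sum(t_null >= t - 1e-7 * (1 + abs(t)))) / (n_replications + 1) else NA_real_
  ranked <- data.frame(
    center = rep_df$center,
    center_x = data$x[rep_df$center],
    center_y = data$y[rep_df$center],
    radius = rep_df$radius,
    n_inside = rep_df$n_in,
    atrisk_inside = rep_df$N_in,
    n_outside = data$n_cases - rep_df$n_in,
    atrisk_outside = data$n - rep_df$N_in,
    log_lr = rep_df$llr,
    expected_cases = expected_cases(data$n_cases, rep_df$N_in, data$n),
    p_value = vapply(rep_df$llr, pval, numeric(1)))
  members <- lapply(seq_len(nrow(ranked)), function(i) {
    d <- sqrt((data$x - ranked$center_x[i])^2 + (data$y - ranked$center_y[i])^2)
    which(d <= ranked$radius[i])
  })
  structure(list(total_cases = data$n_cases, total_atrisk = data$n,
                 primary = ranked[1, , drop = FALSE], ranked = ranked,
                 member_indices = members,
                 t_obs = ranked$log_lr[1], t_null = t_null,
                 n_replications = n_replications, max_radius = max_radius,
                 alpha = alpha, kernel = kernel, seed = seed),
            class = "scan_result")
}

empty_cluster_df <- function() {
  data.frame(center = integer(0), center_x = numeric(0), center_y = numeric(0),
             radius = numeric(0), n_inside = integer(0),
             atrisk_inside = integer(0), n_outside = integer(0),
             atrisk_outside = integer(0), log_lr = numeric(0),
             expected_cases = numeric(0), p_value = numeric(0))
}

# best window per centre for an arbitrary centre set, scored with the true
# labels; plain R, used only for the non-default centers = "all" path
rescore_centers <- function(data, centers, max_radius, kern) {
  rows <- lapply(centers, function(c0) {
    d <- sqrt((data$x - data$x[c0])^2 + (data$y - data$y[c0])^2)
    keep <- d <= max_radius
    radii <- sort(unique(d[keep]))
    best <- list(llr = -Inf, radius = Inf, n_in = 0L, N_in = 0L)
    for (r in radii) {
      inside <- d <= r
      llr <- llr_counts_cpp(sum(data$label[inside] == "case"), sum(inside),
                            sum(data$label[!inside] == "case"), sum(!inside),
                            kern)
      if (llr > best$llr + 1e-12) {
        best <- list(llr = llr, radius = r,
                     n_in = sum(data$label[inside] == "case"),
                     N_in = sum(inside))
      }
    }
    data.frame(center = c0, radius = if (is.finite(best$llr)) best$radius else NA,
               n_in = best$n_in, N_in = best$N_in, llr = best$llr)
  })
  do.call(rbind, rows)
}

#' @export
print.scan_result <- function(x, ...) {
  cat("Bernoulli spatial scan:", x$total_cases, "cases /", x$total_atrisk,
      "at risk; max radius", x$max_radius, "m;",
      x$n_replications, "Monte Carlo replications\n")
  if (is.null(x$primary)) {
    cat("no candidate cluster (risk never elevated inside any window)\n")
  } else {
    p <- x$primary
    cat(sprintf(paste0("most likely cluster: %d cases / %d at risk, radius ",
                       "%.0f m, E = %.2f, p = %s\n"),
                p$n_inside, p$atrisk_inside, p$radius, p$expected_cases,
                ifelse(is.na(p$p_value), "NA", format(round(p$p_value, 3)))))
  }
  invisible(x)
}

#' Plot a scan result over its pattern
#'
#' Controls as grey dots, cases as red dots, reported cluster discs as
#' circles.
#'
#' @param x a \code{scan_result}.
#' @param data the \code{cc_pattern} the scan was run on.
#' @param ... passed to \code{plot}.
#' @export
plot.scan_result <- function(x, data, ...) {
  plot(data$x, data$y, col = ifelse(data$label == "case", "red", "grey40"),
       pch = ifelse(data$label == "case", 19, 1), asp = 1,
       xlab = "x (m)", ylab = "y (m)", ...)
  b <- data$window$boundary
  graphics::polygon(b[, 1], b[, 2], border = "grey60")
  th <- seq(0, 2 * pi, length.out = 181)
  for (i in seq_len(nrow(x$ranked))) {
    graphics::lines(x$ranked$center_x[i] + x$ranked$radius[i] * cos(th),
                    x$ranked$center_y[i] + x$ranked$radius[i] * sin(th),
                    col = "blue")
  }
  invisible(x)
}
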