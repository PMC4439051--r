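#' Difference of K functions, D(s)
#'
#' The case-control clustering statistic of Diggle and Chetwynd:
#' \deqn{D(s) = \hat K_{cases}(s) - \hat K_{controls}(s),}
#' each K estimated on its own sub-pattern over the shared window. Under the
#' null hypothesis that cases are a random sample of the at-risk population,
#' D(s) = 0 at every distance; positive values indicate extra aggregation of
#' cases beyond the (typically inhomogeneous) population pattern.
#'
#' @param data a \code{\link{cc_pattern}} with at least 2 cases and 2 controls.
#' @param s_grid distance grid (meters); default \code{default_s_grid(s_max)}.
#' @param correction edge correction passed to \code{\link{k_function}}.
#' @param s_max grid maximum when \code{s_grid} is missing; default 8000 m.
#' @return numeric vector of D(s) values (m^2), one per grid distance.
#' @export
d_function <- function(data, s_grid = NULL, correction = c("isotropic", "none"),
                       s_max = 8000) {
  stopifnot(inherits(data, "cc_pattern"))
  correction <- match.arg(correction)
  if (data$n_cases < 2 || data$n_controls < 2)
    stop("need at least 2 cases and 2 controls")
  if (is.null(s_grid)) s_grid <- default_s_grid(s_max)
  kc <- k_function(subset_group(data, "case"), s_grid, correction)
  kk <- k_function(subset_group(data, "control"), s_grid, correction)
  kc$k_values - kk$k_values
}

#' Random-labeling Monte Carlo envelope for D(s)
#'
#' Simulates the null distribution of D(s) by random labeling: case/control
#' labels are permuted over the pooled coordinates, holding the number of
#' cases fixed (optionally within matching strata), and D(s) is recomputed
#' for each replicate. Envelopes are the pointwise min/max over replicates
#' (\code{rule = "minmax"}) or the pointwise empirical 2.5\%/97.5\% quantiles
#' (\code{rule = "quantile"}); the observed D(s) is never included in the
#' envelope. With the minmax rule and \code{n_sim} replicates, the pointwise
#' probability of exiting the envelope at a pre-fixed distance is
#' \code{2/(n_sim+1)} under the null.
#'
#' @inheritParams d_function
#' @param n_sim number of random relabelings (>= 19); default 999.
#' @param rule envelope rule, \code{"minmax"} (default) or \code{"quantile"}.
#' @param stratified permute labels within each (region, birth year, sex)
#'   stratum instead of freely; off by default (plain random labeling).
#' @param seed optional integer seed (set before permuting).
#' @return an object of class \code{"dfun_envelope"}: list with
#'   \code{s_grid}, \code{d_values}, \code{lower_envelope},
#'   \code{upper_envelope}, \code{exceed_upper}, \code{exceed_lower},
#'   \code{n_sim}, \code{envelope_rule}, \code{correction}, \code{seed}.
#' @export
random_labeling_envelope <- function(data, s_grid = NULL, n_sim = 999,
                                     rule = c("minmax", "quantile"),
                                     stratified = FALSE,
                                     correction = c("isotropic", "none"),
                                     s_max = 8000, seed = NULL) {
  stopifnot(inherits(data, "cc_pattern"))
  rule <- match.arg(rule)
  correction <- match.arg(correction)
  if (data$n_cases < 2 || data$n_controls < 2)
    stop("need at least 2 cases and 2 controls")
  if (n_sim < 19)
    stop("n_sim must be >= 19 to support a 0.05-level pointwise envelope")
  if (is.null(s_grid)) s_grid <- default_s_grid(s_max)
  s_grid <- as.numeric(s_grid)
  if (!is.null(seed)) set.seed(seed)

  w <- data$window
  pairs <- cc_pairs_cpp(data$x, data$y, w$boundary[, 1], w$boundary[, 2],
                        s_grid, correction == "isotropic")
  obs_lab <- as.integer(data$label == "case")
  labs <- matrix(0L, nrow = data$n, ncol = n_sim + 1L)
  labs[, 1] <- obs_lab
  sid <- if (stratified) stratum_id(data) else NULL
  if (stratified && is.null(sid))
    stop("stratified permutation requires stratum attributes")
  shuffle <- function(z) if (length(z) == 1L) z else sample(z)
  for (r in seq_len(n_sim)) {
    labs[, r + 1] <- if (is.null(sid)) sample(obs_lab) else
      stats::ave(obs_lab, sid, FUN = shuffle)
  }
  dmat <- dfun_perm_cpp(pairs$i, pairs$j, pairs$bin, pairs$w,
                        length(s_grid), w$area, labs)
  d_obs <- dmat[1, ]
  sims <- dmat[-1, , drop = FALSE]
  if (rule == "minmax") {
    lower <- apply(sims, 2, min); upper <- apply(sims, 2, max)
  } else {
    qs <- apply(sims, 2, stats::quantile, probs = c(0.025, 0.975),
                names = FALSE, type = 7)
    lower <- qs[1, ]; upper <- qs[2, ]
  }
  structure(list(s_grid = s_grid, d_values = d_obs,
                 lower_envelope = lower, upper_envelope = upper,
                 exceed_upper = d_obs > upper, exceed_lower = d_obs < lower,
                 n_sim = n_sim, envelope_rule = rule,
                 correction = correction, stratified = stratified,
                 seed = seed), class = "dfun_envelope")
}

#' Interpret a D(s) envelope
#'
#' Pointwise verdict per distance: where the observed D(s) lies above the
#' upper envelope the cases are more aggregated than the controls; below the
#' lower envelope the controls are more aggregated; otherwise the data are
#' consistent with the random-labeling null.
#'
#' @param result a \code{dfun_envelope}.
#' @return factor per grid distance with levels \code{cases_aggregated},
#'   \code{controls_aggregated}, \code{null_consistent}.
#' @export
interpret <- function(result) {
  stopifnot(inherits(result, "dfun_envelope"))
  v <- ifelse(result$exceed_upper, "cases_aggregated",
              ifelse(result$exceed_lower, "controls_aggregated",
                     "null_consistent"))
  factor(v, levels = c("cases_aggregated", "controls_aggregated",
                       "null_consistent"))
}

#' @export
print.dfun_envelope <- function(x, ...) {
  v <- interpret(x)
  cat("D(s) with random-labeling envelope (", x$envelope_rule, ", n_sim = ",
      x$n_sim, ", ", x$correction, " correction)\n", sep = "")
  cat("distances:", length(x$s_grid), "up to", max(x$s_grid), "m\n")
  cat("cases more aggregated at", sum(v == "cases_aggregated"),
      "distance(s); controls at", sum(v == "controls_aggregated"), "\n")
  invisible(x)
}

#' Plot D(s) with its Monte Carlo envelope
#'
#' Observed D(s) as a solid red line, envelope limits as dotted lines.
#'
#' @param x a \code{dfun_envelope}.
#' @param ... passed to \code{plot}.
#' @export
plot.dfun_envelope <- function(x, ...) {
  rng <- range(x$d_values, x$lower_envelope, x$upper_envelope)
  plot(x$s_grid, x$d_values, type = "l", col = "red", ylim = rng,
       xlab = "distance s (m)", ylab = "D(s)", ...)
  graphics::lines(x$s_grid, x$upper_envelope, lty = 3)
  graphics::lines(x$s_grid, x$lower_envelope, lty = 3)
  graphics::abline(h = 0, col = "grey")
  invisible(x)
}
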