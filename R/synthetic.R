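#' Synthetic matched case-control scenarios
#'
#' Describes a generative matched case-control spatial dataset: an
#' inhomogeneous at-risk population drawn from a Gaussian-mixture intensity
#' (emulating regions dominated by a few urban centres), cases drawn under a
#' constant-risk null or with an injected circular excess-risk cluster, and
#' stratum-matched controls at a fixed ratio (default 6 controls per case,
#' matched on region of residence, year of birth and sex).
#'
#' @param window a \code{\link{study_window}}.
#' @param population_centers data frame with columns \code{x}, \code{y},
#'   \code{spread} (Gaussian sd, meters) and \code{weight} (positive mixture
#'   weight) defining the population intensity.
#' @param n_cases number of cases to draw.
#' @param matching_ratio controls per case (>= 1); default 6.
#' @param strata_spec list with \code{birth_years} (integer vector),
#'   \code{sex_prob} (named numeric, \code{M}/\code{F}) and \code{regions}
#'   (named numeric weights). Strata are assigned independently of location.
#' @param injected_cluster optional list with \code{x}, \code{y},
#'   \code{radius} (meters) and \code{relative_risk} (>= 1): inside the disc
#'   a location's case-selection weight is multiplied by the relative risk.
#' @param n_population size of the at-risk location pool to draw; default
#'   \code{8 * n_cases * (matching_ratio + 1)}, large enough that every
#'   stratum can supply its matched controls with high probability even for
#'   fine stratifications (the registry the pool emulates is effectively
#'   unlimited relative to the case series).
#' @param seed optional integer seed used by \code{\link{generate_cc_data}}.
#' @return an object of class \code{"synthetic_scenario"}.
#' @export
synthetic_scenario <- function(window, population_centers, n_cases,
                               matching_ratio = 6,
                               strata_spec = default_strata_spec(),
                               injected_cluster = NULL,
                               n_population = NULL, seed = NULL) {
  stopifnot(inherits(window, "study_window"), n_cases >= 1, matching_ratio >= 1)
  pc <- as.data.frame(population_centers)
  stopifnot(all(c("x", "y", "spread", "weight") %in% names(pc)),
            all(pc$weight > 0), all(pc$spread > 0))
  if (!is.null(injected_cluster)) {
    stopifnot(all(c("x", "y", "radius", "relative_risk") %in% names(injected_cluster)),
              injected_cluster$relative_risk >= 1, injected_cluster$radius > 0)
  }
  if (is.null(n_population))
    n_population <- ceiling(8 * n_cases * (matching_ratio + 1))
  if (n_population < n_cases * (matching_ratio + 1))
    stop("n_population too small to supply cases plus matched controls")
  structure(list(window = window, population_centers = pc,
                 n_cases = as.integer(n_cases),
                 matching_ratio = as.integer(matching_ratio),
                 strata_spec = strata_spec,
                 injected_cluster = injected_cluster,
                 n_population = as.integer(n_population), seed = seed),
            class = "synthetic_scenario")
}

#' @rdname synthetic_scenario
#' @export
default_strata_spec <- function() {
  list(birth_years = 1996:2011,
       sex_prob = c(M = 0.512, F = 0.488),
       regions = c(R1 = 1))
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat("synthetic matched case-control scenario:\n")
  cat(" ", x$n_cases, "cases, 1:", x$matching_ratio, "matched controls, pool of",
      x$n_population, "at-risk locations\n")
  cat(" ", nrow(x$population_centers), "population centre(s)\n")
  if (!is.null(x$injected_cluster))
    cat("  injected cluster: RR", x$injected_cluster$relative_risk, "within",
        x$injected_cluster$radius, "m of (", x$injected_cluster$x, ",",
        x$injected_cluster$y, ")\n")
  invisible(x)
}

#' Draw at-risk locations from a scenario's population intensity
#'
#' Rejection sampling from the Gaussian-mixture intensity truncated to the
#' study window: mixture components are picked by weight, coordinates drawn
#' from the component Gaussian, and draws outside the window discarded.
#'
#' @param scenario a \code{synthetic_scenario}.
#' @param n number of locations; defaults to \code{scenario$n_population}.
#' @return two-column matrix of coordinates (meters).
#' @export
sample_population <- function(scenario, n = scenario$n_population) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  pc <- scenario$population_centers
  w <- scenario$window
  out <- matrix(NA_real_, n, 2)
  got <- 0L
  tries <- 0L
  max_tries <- 1000L
  while (got < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("population intensity places almost no mass in the window ",
           "(rejection-sampling retry cap reached)")
    need <- n - got
    m <- max(need * 2L, 64L)
    comp <- sample.int(nrow(pc), m, replace = TRUE, prob = pc$weight)
    px <- stats::rnorm(m, pc$x[comp], pc$spread[comp])
    py <- stats::rnorm(m, pc$y[comp], pc$spread[comp])
    ok <- points_in_window(px, py, w)
    k <- min(sum(ok), need)
    if (k > 0) {
      out[(got + 1):(got + k), ] <- cbind(px[ok], py[ok])[seq_len(k), ]
      got <- got + k
    }
  }
  colnames(out) <- c("x", "y")
  out
}

#' Assign case labels, strata and matched controls
#'
#' Given a pool of at-risk locations, draws the case locations (uniformly
#' under the null; with selection weight multiplied by the relative risk
#' inside an injected cluster disc), assigns matching strata (region, birth
#' year, sex) independently of location, and samples \code{matching_ratio}
#' controls per case without replacement from the same stratum. Locations
#' that are neither cases nor selected controls are dropped, mirroring a
#' registry study in which only cases and their matched controls are
#' geocoded.
#'
#' @param locations two-column matrix of at-risk coordinates.
#' @param scenario a \code{synthetic_scenario}.
#' @return a \code{\link{cc_pattern}} with exactly
#'   \code{matching_ratio * n_cases} controls, stratum-matched.
#' @export
assign_cases <- function(locations, scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  locations <- as.matrix(locations)
  n <- nrow(locations)
  if (n < scenario$n_cases * (scenario$matching_ratio + 1))
    stop("not enough locations for cases plus matched controls")
  wt <- rep(1, n)
  ic <- scenario$injected_cluster
  if (!is.null(ic)) {
    d <- sqrt((locations[, 1] - ic$x)^2 + (locations[, 2] - ic$y)^2)
    wt[d <= ic$radius] <- ic$relative_risk
  }
  case_idx <- sample.int(n, scenario$n_cases, prob = wt)

  sp <- scenario$strata_spec
  resample <- function(v, prob = NULL)
    v[sample.int(length(v), n, replace = TRUE, prob = prob)]
  region <- resample(names(sp$regions), prob = sp$regions)
  birth_year <- resample(sp$birth_years)
  sex <- resample(names(sp$sex_prob), prob = sp$sex_prob)
  sid <- paste(region, birth_year, sex, sep = "/")

  is_case <- rep(FALSE, n); is_case[case_idx] <- TRUE
  ctrl_idx <- integer(0)
  for (s in unique(sid[is_case])) {
    k <- sum(is_case & sid == s)
    pool <- which(!is_case & sid == s)
    need <- k * scenario$matching_ratio
    if (length(pool) < need)
      stop("stratum exhausted: ", s, " (need ", need, " controls, have ",
           length(pool), ")")
    ctrl_idx <- c(ctrl_idx, if (length(pool) == 1) pool else
      sample(pool, need))
  }
  sel <- c(case_idx, ctrl_idx)
  cc_pattern(locations[sel, 1], locations[sel, 2],
             label = rep(c("case", "control"),
                         c(length(case_idx), length(ctrl_idx))),
             window = scenario$window,
             region = region[sel], birth_year = birth_year[sel],
             sex = sex[sel])
}

#' Generate a complete synthetic matched case-control dataset
#'
#' Seeds the RNG from the scenario (when a seed is recorded), draws the
#' at-risk pool and assigns cases, strata and matched controls. If a rare
#' stratum cannot supply its matched controls from the initial pool, the
#' pool is topped up with further draws from the population intensity and
#' the assignment repeated -- the same remedy a registry study applies when
#' sampled controls fall through (strata are independent of location, so
#' topping up leaves the spatial law of the dataset unchanged).
#'
#' @param scenario a \code{synthetic_scenario}.
#' @return a \code{\link{cc_pattern}}.
#' @export
generate_cc_data <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  pool <- sample_population(scenario)
  err <- NULL
  for (attempt in 1:20) {
    res <- tryCatch(assign_cases(pool, scenario), error = function(e) e)
    if (!inherits(res, "error")) return(res)
    if (!grepl("stratum exhausted", conditionMessage(res))) stop(res)
    err <- res
    pool <- rbind(pool,
                  sample_population(scenario,
                                    ceiling(scenario$n_population / 2)))
  }
  stop(err)
}

#' Privacy jitter of coordinates
#'
#' Replaces the trailing \code{digits} integer digits of every coordinate by
#' a uniformly random number, the coordinate-anonymisation scheme used for
#' confidential geocoded address data:
#' \deqn{x' = \lfloor x / 10^d \rfloor 10^d + u, \quad
#'   u \sim U\{0, \dots, 10^d - 1\},}
#' independently per coordinate. With \code{digits = 1} every coordinate
#' moves by less than 10 m. Points whose jittered position would leave the
#' study window are redrawn (and kept at their original position after 100
#' failed attempts, which only occurs within \code{10^d} m of the boundary).
#'
#' @param data a \code{cc_pattern} or \code{point_pattern} with nonnegative
#'   projected coordinates.
#' @param digits number of trailing integer digits to randomise (>= 1).
#' @return an object of the same class with jittered coordinates.
#' @export
jitter_coordinates <- function(data, digits = 1) {
  stopifnot(inherits(data, "point_pattern"), digits >= 1)
  if (any(data$x < 0) || any(data$y < 0))
    stop("privacy jitter requires nonnegative projected coordinates")
  base <- 10^digits
  jit <- function(v) floor(v / base) * base + sample.int(base, length(v), replace = TRUE) - 1
  x <- jit(data$x); y <- jit(data$y)
  for (attempt in 1:100) {
    bad <- !points_in_window(x, y, data$window)
    if (!any(bad)) break
    x[bad] <- jit(data$x[bad]); y[bad] <- jit(data$y[bad])
  }
  bad <- !points_in_window(x, y, data$window)
  x[bad] <- data$x[bad]; y[bad] <- data$y[bad]
  out <- data
  out$x <- x; out$y <- y
  out
}
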