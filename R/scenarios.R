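#' Default study scenarios
#'
#' Synthetic scenarios mirroring the structure and magnitudes of the Spanish
#' childhood-cancer matched case-control study (see
#' \code{\link{childhood_cancer_counts}}): for each cancer cause and region
#' group, a scenario with the published case count, 6 matched controls per
#' case, and a Gaussian-mixture population intensity dominated by the main
#' urban centres of the region group. Coordinates are on a plausible
#' ETRS89 / UTM 30N scale; the mixtures are controllable stand-ins, not fit
#' to any real population map. All scenarios are null (no injected cluster).
#'
#' @param seed integer master seed; each scenario gets a distinct derived
#'   seed.
#' @param causes subset of causes to build; default all four.
#' @param region_groups subset of region groups; default both.
#' @return named list of \code{\link{synthetic_scenario}} objects, names
#'   \code{"<cause>:<region_group>"}.
#' @export
study_scenarios <- function(seed = 1, causes = NULL, region_groups = NULL) {
  tab <- childhood_cancer_counts()
  if (!is.null(causes)) tab <- tab[tab$cause %in% causes, ]
  if (!is.null(region_groups)) tab <- tab[tab$region_group %in% region_groups, ]
  out <- list()
  for (i in seq_len(nrow(tab))) {
    rg <- tab$region_group[i]
    geo <- region_geometry(rg)
    out[[paste(tab$cause[i], rg, sep = ":")]] <- synthetic_scenario(
      window = geo$window,
      population_centers = geo$centers,
      n_cases = tab$cases[i],
      matching_ratio = 6,
      strata_spec = geo$strata,
      seed = (as.integer(seed) + 173L * i) %% .Machine$integer.max)
  }
  out
}

#' @rdname study_scenarios
#' @param region_group \code{"northeast"} or \code{"madrid"}.
#' @export
region_geometry <- function(region_group = c("northeast", "madrid")) {
  region_group <- match.arg(region_group)
  if (region_group == "northeast") {
    # four contiguous regions; mixture dominated by Barcelona with
    # Zaragoza, Bilbao and Pamplona plus a diffuse rural background
    list(
      window = rect_window(480000, 980000, 4450000, 4800000,
                           crs_tag = "EPSG:25830"),
      centers = data.frame(
        x = c(928000, 676000, 505000, 611000, 730000),
        y = c(4581000, 4613000, 4790000, 4741000, 4640000),
        spread = c(14000, 9000, 8000, 6000, 110000),
        weight = c(0.42, 0.13, 0.12, 0.05, 0.28)),
      strata = list(birth_years = 1996:2011,
                    sex_prob = c(M = 0.512, F = 0.488),
                    regions = c(CAT = 0.63, PV = 0.19, ARA = 0.12,
                                NAV = 0.06)))
  } else {
    list(
      window = rect_window(380000, 500000, 4400000, 4530000,
                           crs_tag = "EPSG:25830"),
      centers = data.frame(
        x = c(441000, 441000),
        y = c(4474000, 4468000),
        spread = c(11000, 45000),
        weight = c(0.72, 0.28)),
      strata = list(birth_years = 2000:2011,
                    sex_prob = c(M = 0.512, F = 0.488),
                    regions = c(MAD = 1)))
  }
}
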