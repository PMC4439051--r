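#' Published summary counts of the Spanish childhood-cancer study
#'
#' Summary counts from the published Spanish childhood-cancer matched
#' case-control study this package's analyses mirror: incident cases aged
#' 0-14 of the four main diagnostic groups (leukemia, central nervous system
#' tumours, Hodgkin and non-Hodgkin lymphoma) in two region groups (the four
#' contiguous North-East regions, and Madrid), each case matched with six
#' birth-registry controls on year of birth, region of residence and sex.
#' For every cause and region group the table also records the most likely
#' cluster reported by the Bernoulli spatial scan: the at-risk individuals
#' and cases inside the window, the window radius, and the Monte Carlo
#' p-value (9999 replications). The underlying geocoded addresses are
#' confidential and not distributed; only these summary counts are public,
#' and they are what the expected-case arithmetic is checked against.
#'
#' @return data frame with columns \code{cause}, \code{region_group},
#'   \code{cases}, \code{controls}, \code{cluster_atrisk} (at-risk
#'   individuals inside the most likely cluster), \code{cluster_cases},
#'   \code{cluster_radius_m} and \code{cluster_p}.
#' @examples
#' tab <- childhood_cancer_counts()
#' with(tab[1, ], expected_cases(cases, cluster_atrisk, cases + controls))
#' @export
childhood_cancer_counts <- function() {
  data.frame(
    cause = rep(c("leukemia", "cns", "hl", "nhl"), each = 2),
    region_group = rep(c("northeast", "madrid"), 4),
    cases = c(638L, 424L, 513L, 201L, 53L, 39L, 144L, 102L),
    controls = c(3828L, 2544L, 3078L, 1206L, 318L, 234L, 864L, 612L),
    cluster_atrisk = c(5L, 8L, 20L, 9L, 3L, 2L, 3L, 4L),
    cluster_cases = c(5L, 6L, 10L, 6L, 3L, 2L, 3L, 4L),
    cluster_radius_m = c(460L, 666L, 886L, 1451L, 124L, 573L, 619L, 643L),
    cluster_p = c(0.074, 0.63, 0.92, 0.54, 0.122, 0.54, 0.48, 0.063))
}
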