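#' Case-control point patterns
#'
#' A labeled planar point set: geocoded case and control addresses over a
#' shared study window, with the matching strata (region of residence, year
#' of birth, sex) carried per point. This is the unit of analysis for both
#' the difference-of-K clustering test and the Bernoulli spatial scan.
#'
#' @param x,y numeric coordinates in meters.
#' @param label character/factor per point, \code{"case"} or \code{"control"}.
#' @param window a \code{\link{study_window}}.
#' @param region,birth_year,sex optional matching-stratum attributes per
#'   point (region code, integer year, \code{"M"}/\code{"F"}).
#' @return an object of class \code{"cc_pattern"}.
#' @export
cc_pattern <- function(x, y, label, window, region = NULL, birth_year = NULL,
                       sex = NULL) {
  pp <- point_pattern(x, y, window)
  label <- as.character(label)
  if (!all(label %in% c("case", "control")))
    stop("labels must be 'case' or 'control'")
  if (length(label) != pp$n) stop("label length must match coordinates")
  chk <- function(v, nm) {
    if (!is.null(v) && length(v) != pp$n)
      stop(nm, " length must match coordinates")
    v
  }
  obj <- structure(list(
    x = pp$x, y = pp$y, n = pp$n, window = window,
    label = label,
    region = chk(region, "region"),
    birth_year = chk(if (is.null(birth_year)) NULL else as.integer(birth_year),
                     "birth_year"),
    sex = chk(sex, "sex"),
    n_cases = sum(label == "case"),
    n_controls = sum(label == "control")), class = c("cc_pattern", "point_pattern"))
  obj
}

#' @export
print.cc_pattern <- function(x, ...) {
  cat("case-control point pattern:", x$n_cases, "cases,",
      x$n_controls, "controls\n")
  print(x$window)
  invisible(x)
}

#' Extract one labeled group as a plain point pattern
#'
#' @param data a \code{cc_pattern}.
#' @param which \code{"case"} or \code{"control"}.
#' @export
subset_group <- function(data, which = c("case", "control")) {
  stopifnot(inherits(data, "cc_pattern"))
  which <- match.arg(which)
  i <- data$label == which
  point_pattern(data$x[i], data$y[i], data$window)
}

# stratum id string per point; NULL when no strata recorded
stratum_id <- function(data) {
  parts <- list(data$region, data$birth_year, data$sex)
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (!length(parts)) return(NULL)
  do.call(paste, c(parts, sep = "/"))
}

#' Check the matched case-control design
#'
#' Verifies that the dataset is consistent with matched sampling: every
#' case's (region, birth year, sex) stratum is shared by at least one
#' control, and optionally that the control:case ratio is exact.
#'
#' @param data a \code{cc_pattern} with stratum attributes.
#' @param ratio if non-\code{NULL}, additionally require
#'   \code{n_controls == ratio * n_cases}.
#' @return \code{TRUE} invisibly, or an error describing the violation.
#' @export
check_matched_design <- function(data, ratio = NULL) {
  stopifnot(inherits(data, "cc_pattern"))
  sid <- stratum_id(data)
  if (is.null(sid)) stop("no stratum attributes recorded")
  case_strata <- unique(sid[data$label == "case"])
  ctrl_strata <- unique(sid[data$label == "control"])
  missing <- setdiff(case_strata, ctrl_strata)
  if (length(missing))
    stop("case stratum without any control: ", missing[1])
  if (!is.null(ratio) && data$n_controls != ratio * data$n_cases)
    stop("control total ", data$n_controls, " is not ", ratio, " x ",
         data$n_cases, " cases")
  invisible(TRUE)
}
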