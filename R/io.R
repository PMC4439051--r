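#' Read a case-control dataset from CSV
#'
#' The standard schema has columns \code{x}, \code{y} (projected meters,
#' period decimal separator), \code{label} (\code{case}/\code{control},
#' case-insensitive) and optionally \code{region}, \code{birth_year},
#' \code{sex}, plus any grouping columns (e.g. \code{cause},
#' \code{region_group}). Malformed rows (non-finite coordinates, unknown
#' labels) are rejected with their line numbers; missing mandatory columns
#' are an error.
#'
#' @param path CSV file path (header row required, UTF-8).
#' @param window a \code{\link{study_window}}; when \code{NULL}, the bounding
#'   box of the points padded by 5\% is used.
#' @return a \code{\link{cc_pattern}}; extra columns are attached as the
#'   \code{extra} element.
#' @export
read_cc_csv <- function(path, window = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("x", "y", "label"), names(df))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  df$x <- suppressWarnings(as.numeric(df$x))
  df$y <- suppressWarnings(as.numeric(df$y))
  df$label <- tolower(trimws(df$label))
  bad <- !is.finite(df$x) | !is.finite(df$y) |
    !(df$label %in% c("case", "control"))
  if (any(bad)) {
    warning("rejected ", sum(bad), " malformed row(s) at line(s): ",
            paste(utils::head(which(bad) + 1L, 20), collapse = ", "))
    df <- df[!bad, , drop = FALSE]
  }
  if (!nrow(df)) stop("no valid rows in ", path)
  if (is.null(window)) window <- bbox_window(df$x, df$y)
  out <- cc_pattern(df$x, df$y, df$label, window,
                    region = df[["region"]],
                    birth_year = df[["birth_year"]],
                    sex = df[["sex"]])
  extra <- df[setdiff(names(df), c("x", "y", "label", "region", "birth_year",
                                   "sex"))]
  if (ncol(extra)) out$extra <- extra
  out
}

bbox_window <- function(x, y) {
  padx <- max(0.05 * diff(range(x)), 1)
  pady <- max(0.05 * diff(range(y)), 1)
  rect_window(min(x) - padx, max(x) + padx, min(y) - pady, max(y) + pady)
}

#' Write a case-control dataset to CSV
#'
#' @param data a \code{\link{cc_pattern}}.
#' @param path output path.
#' @param extra optional data frame of additional columns (e.g. cause).
#' @export
write_cc_csv <- function(data, path, extra = NULL) {
  stopifnot(inherits(data, "cc_pattern"))
  df <- data.frame(x = data$x, y = data$y, label = data$label)
  for (nm in c("region", "birth_year", "sex"))
    if (!is.null(data[[nm]])) df[[nm]] <- data[[nm]]
  if (!is.null(extra)) df <- cbind(df, extra)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a multi-group study dataset
#'
#' Reads a CSV in the standard schema and splits it into one
#' \code{\link{cc_pattern}} per combination of the grouping columns
#' (typically cancer cause and region group), reporting row counts per
#' group.
#'
#' @inheritParams read_cc_csv
#' @param group_by character vector of grouping column names; \code{NULL}
#'   for a single ungrouped pattern.
#' @param quiet suppress the per-group row-count message.
#' @return a named list of \code{cc_pattern}s (or a single pattern when
#'   \code{group_by} is \code{NULL}).
#' @export
read_dataset <- function(path, window = NULL, group_by = NULL, quiet = FALSE) {
  if (is.null(group_by)) return(read_cc_csv(path, window))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(group_by, names(df))
  if (length(miss))
    stop("missing grouping column(s): ", paste(miss, collapse = ", "))
  key <- interaction(df[group_by], drop = TRUE, sep = ":")
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  out <- lapply(split(df, key), function(g) {
    utils::write.csv(g, tmp, row.names = FALSE)
    read_cc_csv(tmp, window)
  })
  if (!quiet)
    message(paste(names(out), vapply(out, function(p) p$n, 0),
                  sep = ": ", collapse = "; "), " points")
  out
}
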