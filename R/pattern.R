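#' Planar point patterns
#'
#' A point pattern is a set of planar locations (meters) observed inside a
#' study window. Duplicate coordinates are allowed: after privacy jitter,
#' distinct individuals may share an address.
#'
#' @param x,y numeric coordinate vectors in meters.
#' @param window a \code{\link{study_window}} containing every point.
#' @return an object of class \code{"point_pattern"} with elements
#'   \code{x}, \code{y}, \code{n} and \code{window}.
#' @examples
#' p <- point_pattern(runif(10, 0, 100), runif(10, 0, 100),
#'                    rect_window(0, 100, 0, 100))
#' intensity(p)
#' @export
point_pattern <- function(x, y, window) {
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(inherits(window, "study_window"), length(x) == length(y))
  if (length(x) && (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y))))
    stop("coordinates must be finite")
  if (length(x)) {
    ok <- points_in_window(x, y, window)
    if (!all(ok))
      stop(sum(!ok), " point(s) fall outside the study window (first: index ",
           which(!ok)[1], ")")
  }
  structure(list(x = x, y = y, n = length(x), window = window),
            class = "point_pattern")
}

#' @export
print.point_pattern <- function(x, ...) {
  cat("planar point pattern:", x$n, "points\n")
  print(x$window)
  invisible(x)
}

#' Intensity of a point pattern
#'
#' The (homogeneous) intensity estimate: number of points divided by the
#' window area, in points per square meter.
#'
#' @param x a \code{point_pattern} (or \code{cc_pattern}).
#' @param ... unused.
#' @export
intensity <- function(x, ...) UseMethod("intensity")

#' @rdname intensity
#' @export
intensity.point_pattern <- function(x, ...) {
  if (x$n < 1) stop("intensity is undefined for an empty pattern")
  x$n / window_area(x$window)
}

#' Pairwise Euclidean distances
#'
#' @param pattern a \code{point_pattern} with at least two points.
#' @return symmetric n x n matrix of distances in meters, zero diagonal.
#' @export
pairwise_distances <- function(pattern) {
  stopifnot(inherits(pattern, "point_pattern"))
  if (pattern$n < 2) stop("need at least 2 points for pairwise distances")
  as.matrix(stats::dist(cbind(pattern$x, pattern$y)))
}

#' Default distance grid
#'
#' 64 equally spaced distances from \code{s_max/64} to \code{s_max}; the
#' 8 km cap is the default maximum distance for the clustering analysis.
#'
#' @param s_max maximum distance in meters.
#' @param n_bins number of grid points.
#' @export
default_s_grid <- function(s_max = 8000, n_bins = 64) {
  stopifnot(s_max > 0, n_bins >= 1)
  seq(s_max / n_bins, s_max, length.out = n_bins)
}

#' Ripley's K function for a planar point pattern
#'
#' Estimates K(s), the expected number of further points within distance s of
#' a typical point, scaled by the intensity: under complete spatial
#' randomness K(s) = pi s^2. The estimator is
#' \deqn{\hat K(s) = \frac{1}{\hat\lambda n} \sum_i \sum_{j \ne i}
#'   w_{ij}\, 1[d_{ij} \le s]}
#' with \eqn{w_{ij} = 1} for \code{correction = "none"} and Ripley's
#' isotropic edge-correction weight for \code{correction = "isotropic"}: the
#' reciprocal of the fraction of the circle centred at i with radius
#' \eqn{d_{ij}} whose circumference lies inside the window, computed by exact
#' circular-arc/polygon intersection.
#'
#' @param pattern a \code{point_pattern} with at least two points.
#' @param s_grid strictly increasing vector of positive distances (meters);
#'   defaults to \code{default_s_grid(s_max)}.
#' @param correction \code{"isotropic"} (default) or \code{"none"}.
#' @param s_max grid maximum used when \code{s_grid} is missing.
#' @return an object of class \code{"k_estimate"}: list with \code{s_grid},
#'   \code{k_values} (m^2), \code{correction} and \code{lambda_hat}.
#' @examples
#' w <- rect_window(0, 10, 0, 10)
#' p <- point_pattern(c(4, 5), c(5, 5), w)
#' k_function(p, s_grid = 2, correction = "none")$k_values  # 50
#' @export
k_function <- function(pattern, s_grid = NULL, correction = c("isotropic", "none"),
                       s_max = 8000) {
  stopifnot(inherits(pattern, "point_pattern"))
  correction <- match.arg(correction)
  if (pattern$n < 2) stop("need at least 2 points to estimate K")
  if (is.null(s_grid)) s_grid <- default_s_grid(s_max)
  s_grid <- as.numeric(s_grid)
  if (any(s_grid <= 0)) stop("distances in s_grid must be positive")
  if (is.unsorted(s_grid, strictly = TRUE)) stop("s_grid must be strictly increasing")
  w <- pattern$window
  k <- kfun_cpp(pattern$x, pattern$y, w$boundary[, 1], w$boundary[, 2],
                s_grid, w$area, correction == "isotropic")
  structure(list(s_grid = s_grid, k_values = k, correction = correction,
                 lambda_hat = pattern$n / w$area),
            class = "k_estimate")
}

#' @export
print.k_estimate <- function(x, ...) {
  cat("K-function estimate (", x$correction, " correction), ",
      length(x$s_grid), " distances up to ", max(x$s_grid), " m\n", sep = "")
  cat("intensity estimate:", format(x$lambda_hat, digits = 4), "points/m^2\n")
  invisible(x)
}

#' @export
plot.k_estimate <- function(x, ..., csr = TRUE) {
  plot(x$s_grid, x$k_values, type = "l", xlab = "distance s (m)",
       ylab = expression(hat(K)(s)), ...)
  if (csr) graphics::lines(x$s_grid, pi * x$s_grid^2, lty = 3)
  invisible(x)
}
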