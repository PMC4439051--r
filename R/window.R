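#' Study windows
#'
#' A study window is a simple (non-self-intersecting) polygon in planar
#' projected coordinates, in meters. Every pattern analysed by this package
#' is attached to a window; points on the boundary count as inside. The CRS
#' tag is carried as free-text metadata (e.g. \code{"EPSG:25830"} for
#' ETRS89 / UTM zone 30N) and never interpreted.
#'
#' @param boundary two-column numeric matrix (or data frame) of polygon
#'   vertices in order, in meters. The ring must not repeat its first vertex.
#' @param crs_tag optional character tag recording the projection.
#' @return an object of class \code{"study_window"} with elements
#'   \code{boundary}, \code{area} (m^2) and \code{crs_tag}.
#' @examples
#' w <- rect_window(0, 1000, 0, 1000)
#' window_area(w)
#' @export
study_window <- function(boundary, crs_tag = NULL) {
  boundary <- as.matrix(boundary)
  if (!is.numeric(boundary) || ncol(boundary) != 2 || nrow(boundary) < 3)
    stop("boundary must be a numeric matrix with >= 3 rows and 2 columns")
  if (anyNA(boundary) || any(!is.finite(boundary)))
    stop("boundary vertices must be finite")
  # drop a repeated closing vertex if supplied
  n <- nrow(boundary)
  if (all(boundary[1, ] == boundary[n, ])) boundary <- boundary[-n, , drop = FALSE]
  if (nrow(boundary) < 3) stop("boundary must have >= 3 distinct vertices")
  if (self_intersects(boundary)) stop("boundary polygon is self-intersecting")
  a <- shoelace_area(boundary)
  if (a < 0) { boundary <- boundary[rev(seq_len(nrow(boundary))), ]; a <- -a }
  if (a <= 0) stop("boundary polygon has zero area")
  structure(list(boundary = boundary, area = a, crs_tag = crs_tag),
            class = "study_window")
}

#' @rdname study_window
#' @param xmin,xmax,ymin,ymax rectangle limits in meters.
#' @export
rect_window <- function(xmin, xmax, ymin, ymax, crs_tag = NULL) {
  stopifnot(xmax > xmin, ymax > ymin)
  study_window(cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax)),
               crs_tag = crs_tag)
}

#' @rdname study_window
#' @param w a \code{study_window}.
#' @export
window_area <- function(w) {
  stopifnot(inherits(w, "study_window"))
  w$area
}

shoelace_area <- function(b) {
  x <- b[, 1]; y <- b[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

# brute segment-crossing check; windows have few vertices so O(V^2) is fine
self_intersects <- function(b) {
  n <- nrow(b)
  seg <- cbind(b, b[c(2:n, 1), , drop = FALSE])
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n   # wrap-around edge is adjacent to edge 1
    if (i + 2 > jmax) next
    for (j in (i + 2):jmax) {
      p <- seg[i, ]; q <- seg[j, ]
      d1 <- cross(p[1], p[2], p[3], p[4], q[1], q[2])
      d2 <- cross(p[1], p[2], p[3], p[4], q[3], q[4])
      d3 <- cross(q[1], q[2], q[3], q[4], p[1], p[2])
      d4 <- cross(q[1], q[2], q[3], q[4], p[3], p[4])
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' Point-in-window test
#'
#' Tests whether points fall inside (or on the boundary of) a study window.
#'
#' @param x,y numeric coordinate vectors in meters.
#' @param w a \code{study_window}.
#' @return logical vector; boundary points are \code{TRUE}.
#' @export
points_in_window <- function(x, y, w) {
  stopifnot(inherits(w, "study_window"))
  pip_cpp(as.numeric(x), as.numeric(y), w$boundary[, 1], w$boundary[, 2])
}

#' @export
print.study_window <- function(x, ...) {
  cat("study window:", nrow(x$boundary), "vertices, area",
      format(x$area, big.mark = ","), "m^2")
  if (!is.null(x$crs_tag)) cat(" [", x$crs_tag, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Read a study window from GeoJSON or WKT
#'
#' \code{read_window_geojson} reads the first Polygon geometry found in a
#' GeoJSON file (Polygon, Feature or FeatureCollection); only the exterior
#' ring is used. \code{wkt_window} parses a \code{POLYGON ((x y, ...))}
#' well-known-text string.
#'
#' @param path path to a GeoJSON file.
#' @param crs_tag optional CRS tag to attach.
#' @return a \code{study_window}.
#' @export
read_window_geojson <- function(path, crs_tag = NULL) {
  g <- jsonlite::read_json(path, simplifyVector = FALSE)
  poly <- find_polygon(g)
  if (is.null(poly)) stop("no Polygon geometry found in ", path)
  ring <- do.call(rbind, lapply(poly[[1]], function(p) c(p[[1]], p[[2]])))
  study_window(ring, crs_tag = crs_tag)
}

find_polygon <- function(g) {
  if (is.list(g) && identical(g$type, "Polygon")) return(g$coordinates)
  if (is.list(g) && identical(g$type, "Feature")) return(find_polygon(g$geometry))
  if (is.list(g) && identical(g$type, "FeatureCollection")) {
    for (f in g$features) {
      p <- find_polygon(f)
      if (!is.null(p)) return(p)
    }
  }
  NULL
}

#' @rdname read_window_geojson
#' @param wkt a WKT \code{POLYGON} string.
#' @export
wkt_window <- function(wkt, crs_tag = NULL) {
  m <- regmatches(wkt, regexpr("POLYGON\\s*\\(\\(([^)]*)\\)", wkt, ignore.case = TRUE))
  if (length(m) == 0) stop("not a WKT POLYGON string")
  inner <- sub(".*\\(\\(", "", sub("\\)$", "", m))
  parts <- strsplit(trimws(strsplit(inner, ",")[[1]]), "\\s+")
  ring <- do.call(rbind, lapply(parts, function(p) as.numeric(p[1:2])))
  if (anyNA(ring)) stop("could not parse WKT coordinates")
  study_window(ring, crs_tag = crs_tag)
}

#' Write a window or cluster discs as GeoJSON
#'
#' @param w a \code{study_window}.
#' @param path output file path.
#' @export
write_window_geojson <- function(w, path) {
  stopifnot(inherits(w, "study_window"))
  ring <- rbind(w$boundary, w$boundary[1, ])
  g <- list(type = "Polygon",
            coordinates = list(lapply(seq_len(nrow(ring)), function(i) ring[i, ])))
  jsonlite::write_json(g, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
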