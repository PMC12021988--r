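#' @include AllClasses.R
NULL

# ---- planar polygon utilities ------------------------------------------
# Polygons are n x 2 numeric matrices of vertices in um; the first vertex is
# not repeated and edges wrap from the last vertex back to the first.

asPolygon <- function(p) {
  p <- as.matrix(p)
  if (!is.numeric(p) || ncol(p) != 2)
    stop("a polygon must be a two-column numeric matrix")
  # drop a repeated closing vertex if the caller supplied one
  n <- nrow(p)
  if (n >= 2 && all(p[1, ] == p[n, ])) p <- p[-n, , drop = FALSE]
  if (nrow(p) < 3) stop("degenerate polygon: fewer than 3 distinct vertices")
  storage.mode(p) <- "double"
  p
}

#' Polygon area, centroid and containment
#'
#' Shoelace area (always positive, independent of vertex orientation),
#' area-weighted centroid, even-odd point containment (points exactly on the
#' boundary count as inside) and a simplicity check for planar polygons given
#' as two-column vertex matrices in micrometres with the first vertex not
#' repeated.
#'
#' @param poly polygon, an n x 2 numeric matrix.
#' @param pts points, an m x 2 numeric matrix (or a length-2 vector).
#' @return \code{polygonArea}: area in um^2. \code{polygonCentroid}: length-2
#'   numeric. \code{pointsInPolygon}: logical vector. \code{polygonIsSimple}:
#'   logical(1). \code{pointPolygonDistance}: numeric vector of distances
#'   from each point to the polygon boundary curve.
#' @examples
#' sq <- cbind(c(0, 100, 100, 0), c(0, 0, 100, 100))
#' polygonArea(sq)
#' pointsInPolygon(rbind(c(50, 50), c(150, 50)), sq)
#' @export
polygonArea <- function(poly) {
  p <- asPolygon(poly)
  n <- nrow(p)
  j <- c(2:n, 1)
  abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
}

#' @rdname polygonArea
#' @export
polygonCentroid <- function(poly) {
  p <- asPolygon(poly)
  n <- nrow(p)
  j <- c(2:n, 1)
  cr <- p[, 1] * p[j, 2] - p[j, 1] * p[, 2]
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(p))
  c(sum((p[, 1] + p[j, 1]) * cr), sum((p[, 2] + p[j, 2]) * cr)) / (6 * a)
}

#' @rdname polygonArea
#' @export
pointsInPolygon <- function(pts, poly) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  pts <- as.matrix(pts)
  storage.mode(pts) <- "double"
  cpp_points_in_polygon(pts, asPolygon(poly)) == 1L
}

#' @rdname polygonArea
#' @export
polygonIsSimple <- function(poly) {
  cpp_polygon_is_simple(asPolygon(poly))
}

#' @rdname polygonArea
#' @export
pointPolygonDistance <- function(pts, poly) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  pts <- as.matrix(pts)
  storage.mode(pts) <- "double"
  cpp_point_polygon_distance(pts, asPolygon(poly))
}

#' Minimal distance between two polygon boundary curves
#'
#' The minimum Euclidean distance between the boundary curves of two simple
#' polygons, evaluated over all segment pairs (not vertices only). Returns 0
#' when the curves touch or cross -- a nucleus sharing a point with, or
#' sticking out of, the islet boundary is a first neighbour of the border.
#' This is the distance that drives the mantle/core rule: a cell is a mantle
#' cell when the minimal distance between its nuclear boundary and the islet
#' boundary is strictly below the threshold d_min.
#'
#' @param a,b polygons as two-column vertex matrices (um), first vertex not
#'   repeated. Both must have at least 3 vertices.
#' @return The minimum boundary-to-boundary distance in um (>= 0).
#' @examples
#' islet <- cbind(c(0, 100, 100, 0), c(0, 0, 100, 100))
#' nucleus <- cbind(c(45, 55, 55, 45), c(45, 45, 55, 55))
#' polygonMinDistance(nucleus, islet) # 45
#' @seealso \code{\link{classifyPosition}}, \code{\link{annotatePositions}}
#' @export
polygonMinDistance <- function(a, b) {
  cpp_polygon_min_distance(asPolygon(a), asPolygon(b))
}

# regular-polygon approximation of a circle, used when a tabular export has
# no nuclear boundary column and a disc must be substituted
discPolygon <- function(center, radius, nVertices = 16L) {
  ang <- seq(0, 2 * pi, length.out = nVertices + 1L)[-(nVertices + 1L)]
  cbind(center[1] + radius * cos(ang), center[2] + radius * sin(ang))
}
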