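# Planar geometry helpers. All coordinates are projected metres; no lat/lon math.

#' Test points against a polygon
#'
#' Even-odd (ray casting) point-in-polygon test for a simple polygon given as a
#' data frame of vertices (closing edge implied).
#'
#' @param px,py Numeric vectors of point coordinates (m).
#' @param poly Data frame with columns `x`, `y` (polygon ring, not repeated).
#' @return Logical vector, `TRUE` for points inside (boundary points may fall
#'   either way at floating-point resolution).
#' @export
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  xs <- poly$x; ys <- poly$y
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((ys[i] > py) != (ys[j] > py)) &
      (px < (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# distance from points to a segment (x1,y1)-(x2,y2)
dist_point_segment <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return(sqrt((px - x1)^2 + (py - y1)^2))
  t <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2))
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

#' Distance from points to a polygon
#'
#' Zero for points inside the polygon, otherwise the minimum Euclidean
#' distance to its boundary.
#'
#' @inheritParams point_in_polygon
#' @return Numeric vector of distances (m).
#' @export
dist_to_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  d <- rep(Inf, length(px))
  j <- n
  for (i in seq_len(n)) {
    d <- pmin(d, dist_point_segment(px, py, poly$x[j], poly$y[j], poly$x[i], poly$y[i]))
    j <- i
  }
  d[point_in_polygon(px, py, poly)] <- 0
  d
}
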