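# Planar geometry primitives: point-to-segment distance and point-in-polygon.
# All coordinates are planar meters (the surveillance system is recorded in a
# projected coordinate system, so no datum handling is needed or done).

#' Minimum distance from points to a set of road segments
#'
#' Computes, for each point, the minimum Euclidean distance to any polyline
#' segment of a road network.  Roads are centerline segments; a distance of 0
#' means the point lies exactly on a road.
#'
#' @param x,y numeric vectors of point coordinates (meters).
#' @param roads a data frame of segments with columns `x1`, `y1`, `x2`, `y2`
#'   (as produced by [generate_landscape()] or [read_roads_geojson()]).
#' @return numeric vector of distances (meters), same length as `x`.
#' @examples
#' roads <- data.frame(x1 = 0, y1 = 0, x2 = 10, y2 = 0)
#' nearest_road_distance(3, 4, roads)   # 4: perpendicular foot on segment
#' nearest_road_distance(13, 4, roads)  # 5: 3-4-5 to the (10, 0) endpoint
#' @export
nearest_road_distance <- function(x, y, roads) {
  if (is.null(roads) || nrow(roads) == 0L)
    stop_fmt("road set is empty: nearest_road_distance requires at least one segment")
  stopifnot(length(x) == length(y))
  n <- length(x)
  out <- rep(Inf, n)
  for (s in seq_len(nrow(roads))) {
    d <- dist_point_segment(x, y, roads$x1[s], roads$y1[s], roads$x2[s], roads$y2[s])
    out <- pmin(out, d)
  }
  out
}

# Vectorized over points; one segment.
dist_point_segment <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  L2 <- dx * dx + dy * dy
  if (L2 == 0) return(sqrt((px - x1)^2 + (py - y1)^2))
  t <- ((px - x1) * dx + (py - y1) * dy) / L2
  t <- pmin(1, pmax(0, t))
  qx <- x1 + t * dx; qy <- y1 + t * dy
  sqrt((px - qx)^2 + (py - qy)^2)
}

# Foot of the perpendicular onto the nearest segment (used to snap sampling
# tubes onto road centerlines).  Returns list(x, y, dist).
project_to_roads <- function(x, y, roads) {
  n <- length(x)
  best <- rep(Inf, n); bx <- x; by <- y
  for (s in seq_len(nrow(roads))) {
    x1 <- roads$x1[s]; y1 <- roads$y1[s]; x2 <- roads$x2[s]; y2 <- roads$y2[s]
    dx <- x2 - x1; dy <- y2 - y1
    L2 <- dx * dx + dy * dy
    t <- if (L2 == 0) rep(0, n) else pmin(1, pmax(0, ((x - x1) * dx + (y - y1) * dy) / L2))
    qx <- x1 + t * dx; qy <- y1 + t * dy
    d <- sqrt((x - qx)^2 + (y - qy)^2)
    upd <- d < best
    best[upd] <- d[upd]; bx[upd] <- qx[upd]; by[upd] <- qy[upd]
  }
  list(x = bx, y = by, dist = best)
}

# Even-odd ray casting, vectorized over points, for one closed ring (n x 2
# matrix; first and last vertex need not coincide).  Points lying on an edge
# are reported in `boundary` and counted as inside.
point_in_ring <- function(px, py, ring, tol = 1e-9) {
  nv <- nrow(ring)
  if (all(ring[1, ] == ring[nv, ])) { ring <- ring[-nv, , drop = FALSE]; nv <- nv - 1L }
  inside <- rep(FALSE, length(px))
  boundary <- rep(FALSE, length(px))
  j <- nv
  for (i in seq_len(nv)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]; xj <- ring[j, 1]; yj <- ring[j, 2]
    # boundary: point within tol of segment i-j
    boundary <- boundary | (dist_point_segment(px, py, xi, yi, xj, yj) <= tol)
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses & !is.na(crosses))
    j <- i
  }
  inside | boundary
}

rect_ring <- function(xmin, xmax, ymin, ymax) {
  cbind(c(xmin, xmax, xmax, xmin, xmin), c(ymin, ymin, ymax, ymax, ymin))
}
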