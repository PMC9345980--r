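# Independent oracles used across the suite.  These are deliberately written
# as plain scalar loops / textbook recursions, separate from the package's
# vectorized implementations.

# Cox-de Boor recursion for one B-spline basis function (half-open intervals;
# evaluate strictly inside the knot range).
cox_de_boor <- function(x, i, p, t) {
  if (p == 0) return(as.numeric(t[i] <= x & x < t[i + 1]))
  a <- 0; b <- 0
  if (t[i + p] > t[i])
    a <- (x - t[i]) / (t[i + p] - t[i]) * cox_de_boor(x, i, p - 1, t)
  if (t[i + p + 1] > t[i + 1])
    b <- (t[i + p + 1] - x) / (t[i + p + 1] - t[i + 1]) * cox_de_boor(x, i + 1, p - 1, t)
  a + b
}

oracle_bspline_row <- function(x, def) {
  vapply(seq_len(def$k), function(i) cox_de_boor(x, i, def$degree, def$knots), 0)
}

# Scalar exhaustive point-to-road distance (projection formula per segment).
oracle_road_dist <- function(px, py, roads) {
  best <- Inf
  for (s in seq_len(nrow(roads))) {
    ax <- roads$x1[s]; ay <- roads$y1[s]
    vx <- roads$x2[s] - ax; vy <- roads$y2[s] - ay
    L2 <- vx^2 + vy^2
    t <- if (L2 == 0) 0 else max(0, min(1, ((px - ax) * vx + (py - ay) * vy) / L2))
    d <- sqrt((px - (ax + t * vx))^2 + (py - (ay + t * vy))^2)
    if (d < best) best <- d
  }
  best
}

# Densification oracle: minimum distance to points sampled every `h` meters
# along each segment (upper bound on the true distance).
densified_road_dist <- function(px, py, roads, h = 0.02) {
  best <- Inf
  for (s in seq_len(nrow(roads))) {
    L <- sqrt((roads$x2[s] - roads$x1[s])^2 + (roads$y2[s] - roads$y1[s])^2)
    t <- seq(0, 1, length.out = max(2, ceiling(L / h) + 1))
    d <- sqrt((px - (roads$x1[s] + t * (roads$x2[s] - roads$x1[s])))^2 +
              (py - (roads$y1[s] + t * (roads$y2[s] - roads$y1[s])))^2)
    best <- min(best, min(d))
  }
  best
}

# Scalar even-odd (crossing-number) point-in-polygon.
oracle_point_in_poly <- function(px, py, ring) {
  nv <- nrow(ring)
  if (all(ring[1, ] == ring[nv, ])) { ring <- ring[-nv, , drop = FALSE]; nv <- nv - 1 }
  inside <- FALSE
  j <- nv
  for (i in seq_len(nv)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]; xj <- ring[j, 1]; yj <- ring[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- !inside
    j <- i
  }
  inside
}

# Brute-force cell binning: scan every cell rectangle (half-open, top/right
# boundary of the grid closed).
oracle_cell_of <- function(x, y, grid) {
  cs <- grid$cell_size
  for (i in seq_len(grid$n_rows) - 1L) for (j in seq_len(grid$n_cols) - 1L) {
    x0 <- grid$origin_x + j * cs; y0 <- grid$origin_y + i * cs
    xin <- x >= x0 & (x < x0 + cs || (j == grid$n_cols - 1L && x <= x0 + cs))
    yin <- y >= y0 & (y < y0 + cs || (i == grid$n_rows - 1L && y <= y0 + cs))
    if (xin && yin) return(c(i, j))
  }
  c(NA_integer_, NA_integer_)
}

# Printed surveillance contingency table: categories x (USIRL, SIRH).
TABLE1_COUNTS <- matrix(
  c(668, 1146,
    372, 1371,
    714, 1016,
    424, 769,
    155, 283),
  ncol = 2, byrow = TRUE,
  dimnames = list(c("transportation", "agriculture", "natural",
                    "change", "artificial"),
                  c("USIRL", "SIRH")))
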