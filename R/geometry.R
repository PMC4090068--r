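# Minimal planar geometry for the synthetic island. Coordinates are meters in
# an arbitrary projected CRS centred on the island. No spatial package in the
# stack provides these few primitives without pulling a full GIS, so they are
# implemented directly and tested against brute-force oracles.

# Closed polygon as a two-column matrix (x, y), vertices counter-clockwise,
# first vertex not repeated.

# Shoelace area (m2); positive for counter-clockwise rings.
polygon_area_m2 <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(seq_len(nrow(poly))[-1], 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Ray-casting (even-odd) point-in-polygon, vectorised over points.
points_in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  px <- poly[, 1]; py <- poly[, 2]
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((py[i] > y) != (py[j] > y)) &
      (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Intersect the vertical line x = x0 with a simple polygon: returns a matrix
# of (y_low, y_high) chord intervals (0 rows if the line misses the polygon).
vertical_chords <- function(poly, x0) {
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  j <- c(2:n, 1)
  ycross <- numeric(0)
  for (i in seq_len(n)) {
    x1 <- xs[i]; x2 <- xs[j[i]]
    if ((x1 <= x0 && x2 > x0) || (x2 <= x0 && x1 > x0)) {
      t <- (x0 - x1) / (x2 - x1)
      ycross <- c(ycross, ys[i] + t * (ys[j[i]] - ys[i]))
    }
  }
  if (length(ycross) < 2) return(matrix(numeric(0), ncol = 2))
  ycross <- sort(ycross)
  matrix(ycross, ncol = 2, byrow = TRUE)
}

# Elliptical island polygon with the long axis along x. Area in km2; vertices
# returned in meters.
make_island_polygon <- function(area_km2, aspect = 2.6, n_vertices = 256) {
  b_km <- sqrt(area_km2 / (pi * aspect))
  a_km <- aspect * b_km
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  cbind(km_to_m(a_km) * cos(th), km_to_m(b_km) * sin(th))
}

# Uniform points inside a polygon by bounding-box rejection, with an optional
# hard-core minimum separation (meters) against `existing` and among the new
# points themselves.
runif_in_polygon <- function(n, poly, min_sep_m = 0, existing = NULL,
                             max_tries = 20000L) {
  if (n == 0) return(cbind(x = numeric(0), y = numeric(0)))
  bx <- range(poly[, 1]); by <- range(poly[, 2])
  acc <- if (is.null(existing)) matrix(numeric(0), ncol = 2) else existing
  out <- matrix(numeric(0), ncol = 2)
  tries <- 0L
  while (nrow(out) < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      fail_input("could not place points at the requested minimum separation")
    m <- max(2L * (n - nrow(out)), 16L)
    cx <- runif(m, bx[1], bx[2]); cy <- runif(m, by[1], by[2])
    ok <- points_in_polygon(cx, cy, poly)
    cx <- cx[ok]; cy <- cy[ok]
    for (i in seq_along(cx)) {
      if (nrow(out) >= n) break
      if (min_sep_m > 0 && nrow(acc) > 0) {
        d2 <- (acc[, 1] - cx[i])^2 + (acc[, 2] - cy[i])^2
        if (min(d2) < min_sep_m^2) next
      }
      out <- rbind(out, c(cx[i], cy[i]))
      acc <- rbind(acc, c(cx[i], cy[i]))
    }
  }
  colnames(out) <- c("x", "y")
  out
}
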