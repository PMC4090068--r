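# Independent oracles used across the suite. Each reimplements the quantity
# it checks from a different formulation than the package code.

# Closed-form half-normal effective strip width (the package integrates
# numerically): mu = sigma * sqrt(pi/2) * erf(w / (sigma * sqrt(2))).
esw_halfnormal_closed <- function(sigma, w) {
  sigma * sqrt(pi / 2) * (2 * pnorm(w / sigma) - 1)
}

# Exhaustive-grid oracle for the two-occasion closed-population integer MLE,
# written from the history-level multinomial likelihood (cells 11/10/01/00
# with probabilities p1p2, p1q2, q1p2, q1q2 and p_t profiled at n_t/N)
# rather than the package's concentrated product-binomial form.
mt_mle_grid_oracle <- function(n1, n2, m, n_max = NULL) {
  M <- n1 + n2 - m
  if (is.null(n_max)) n_max <- max(200L, 50L * M)
  x11 <- m; x10 <- n1 - m; x01 <- n2 - m
  ll <- vapply(M:n_max, function(N) {
    p1 <- n1 / N; p2 <- n2 / N
    x00 <- N - M
    cells <- c(x11, x10, x01, x00)
    probs <- c(p1 * p2, p1 * (1 - p2), (1 - p1) * p2, (1 - p1) * (1 - p2))
    keep <- cells > 0
    lgamma(N + 1) - sum(lgamma(cells + 1)) +
      sum(cells[keep] * log(probs[keep]))
  }, 0)
  (M:n_max)[which.max(ll)]
}

# Sparse flood-fill connected-component count (8-connectivity) over the TRUE
# pixels of a logical matrix; independent of EBImage.
flood_fill_components <- function(mask) {
  idx <- which(mask)
  if (length(idx) == 0) return(0L)
  nr <- nrow(mask)
  rows <- (idx - 1) %% nr + 1
  cols <- (idx - 1) %/% nr + 1
  key <- paste(rows, cols)
  lookup <- seq_along(idx)
  names(lookup) <- key
  seen <- rep(FALSE, length(idx))
  comps <- 0L
  for (s in seq_along(idx)) {
    if (seen[s]) next
    comps <- comps + 1L
    queue <- s
    seen[s] <- TRUE
    while (length(queue) > 0) {
      cur <- queue[1]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        nb <- lookup[paste(rows[cur] + dr, cols[cur] + dc)]
        if (!is.na(nb) && !seen[nb]) {
          seen[nb] <- TRUE
          queue <- c(queue, nb)
        }
      }
    }
  }
  comps
}

# Grid-integration oracle for the expected number of line-transect
# detections: E[n] = N * mean over island cells of detection probability.
expected_detections_oracle <- function(scene, sigma_m, truncation_m,
                                       cell_m = 200) {
  poly <- scene$island
  bx <- range(poly[, 1]); by <- range(poly[, 2])
  gx <- seq(bx[1] + cell_m / 2, bx[2], by = cell_m)
  gy <- seq(by[1] + cell_m / 2, by[2], by = cell_m)
  gr <- expand.grid(x = gx, y = gy)
  inside <- polarcensus:::points_in_polygon(gr$x, gr$y, poly)
  gr <- gr[inside, ]
  d <- apply(abs(outer(gr$x, scene$transects$x_m, "-")), 1, min)
  p <- ifelse(d <= truncation_m, exp(-d^2 / (2 * sigma_m^2)), 0)
  nrow(scene$bears) * mean(p)
}

# Observer fixture reproducing the satellite worked example: 38 shared
# points, 52 A-only, 2 B-only, all on a 1-km grid so matching is exact.
make_fixture_tables <- function() {
  n_total <- 92
  gx <- rep(seq_len(10) * 1000, length.out = n_total)
  gy <- rep(seq_len(10) * 1000, each = 10)[seq_len(n_total)]
  shared <- 1:38; a_only <- 39:90; b_only <- 91:92
  a_idx <- c(shared, a_only); b_idx <- c(shared, b_only)
  list(
    A = data.frame(point_id = paste0("A", seq_along(a_idx)), observer = "A",
                   x_m = gx[a_idx], y_m = gy[a_idx]),
    B = data.frame(point_id = paste0("B", seq_along(b_idx)), observer = "B",
                   x_m = gx[b_idx], y_m = gy[b_idx]))
}

# A detection_fit shell with fixed (not estimated) parameters, for testing
# goodness of fit against a known model.
make_fixed_fit <- function(key, theta, truncation_m, data) {
  spec <- detection_spec(key, truncation_m = truncation_m)
  structure(list(spec = spec, label = paste0(key, "/fixed"), theta = theta,
                 vcov = matrix(NA, length(theta), length(theta)),
                 esw_m = NA, se_esw_m = NA, p = NA, se_p = NA,
                 p_i = NULL, sigma_i = NULL, logLik = NA, K = 0L,
                 n = nrow(data), data = data, converged = TRUE),
            class = "detection_fit")
}

# Truncated half-normal perpendicular distances.
rhalfnorm_trunc <- function(n, sigma, w) {
  out <- numeric(0)
  while (length(out) < n) {
    z <- abs(rnorm(2 * n, 0, sigma))
    out <- c(out, z[z <= w])
  }
  out[seq_len(n)]
}

# Minimal sightings table wrapper around a distance vector.
as_sightings <- function(x, group_size = 1, stratum = "Rowley",
                         transect_id = 1) {
  n <- length(x)
  data.frame(transect_id = rep_len(transect_id, n), stratum = stratum,
             perp_distance_m = x, group_size = rep_len(group_size, n),
             vis = sample(c("poor/fair", "excellent"), n, TRUE),
             light = sample(c("overcast", "mostly cloudy",
                              "partly cloudy/clear"), n, TRUE))
}
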