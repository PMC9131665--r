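# Independent geometry oracles, deliberately implemented differently from
# the package's clipping path.

# shoelace via the "x * (y_next - y_prev)" form
shoelace_oracle <- function(ring) {
  n <- nrow(ring)
  ynext <- ring[c(2:n, 1L), 2L]
  yprev <- ring[c(n, 1:(n - 1L)), 2L]
  abs(sum(ring[, 1L] * (ynext - yprev))) / 2
}

perimeter_oracle <- function(ring) {
  n <- nrow(ring)
  nxt <- ring[c(2:n, 1L), , drop = FALSE]
  sum(sqrt((nxt[, 1L] - ring[, 1L])^2 + (nxt[, 2L] - ring[, 2L])^2))
}

# even-odd ray crossing, vectorized over query points
point_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1L]; yi <- ring[i, 2L]
    xj <- ring[j, 1L]; yj <- ring[j, 2L]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Monte-Carlo buffer composition oracle: uniform samples in the disk,
# per-polygon membership (holes excluded), per-category area in km2.
mc_buffer_oracle <- function(px, py, fields, radius_m, nsim = 1e5,
                             seed = 1) {
  set.seed(seed)
  r <- radius_m * sqrt(runif(nsim))
  th <- runif(nsim, 0, 2 * pi)
  qx <- px + r * cos(th)
  qy <- py + r * sin(th)
  disk_km2 <- pi * (radius_m / 1000)^2
  cats <- peckyrice::land_use_categories()
  phat <- setNames(rep(0, length(cats)), cats)
  for (i in seq_len(nrow(fields))) {
    g <- fields$geometry[[i]]
    inside <- point_in_ring(qx, qy, g[[1L]])
    if (length(g) > 1L) {
      for (h in g[-1L]) inside <- inside & !point_in_ring(qx, qy, h)
    }
    phat[fields$category[i]] <- phat[fields$category[i]] + mean(inside)
  }
  # + disk/nsim guards the zero-probability categories
  list(est = disk_km2 * phat,
       se = disk_km2 * sqrt(phat * pmax(1 - phat, 0) / nsim) + disk_km2 / nsim)
}

rect_ring_test <- function(xmin, ymin, xmax, ymax) {
  cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax))
}

# random convex ring via the convex hull of random points
random_convex_ring <- function(cx, cy, rmax, n = 12, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- cx + runif(n, -rmax, rmax)
  y <- cy + runif(n, -rmax, rmax)
  h <- grDevices::chull(x, y)
  cbind(x[h], y[h])
}
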