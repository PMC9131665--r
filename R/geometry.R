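# Internal planar geometry primitives.
#
# A "ring" is an open 2-column numeric matrix (x, y) in meters: the closing
# vertex is NOT repeated. A polygon is a list of rings, the first exterior,
# the rest holes. All clipping goes through Sutherland-Hodgman against a
# CONVEX clip ring, which is exact (up to float) for any simple subject.

ring_area_signed <- function(ring) {
  x <- ring[, 1L]
  y <- ring[, 2L]
  xn <- c(x[-1L], x[1L])
  yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

ring_area <- function(ring) abs(ring_area_signed(ring))

ring_perimeter <- function(ring) {
  d <- ring - ring[c(2:nrow(ring), 1L), , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}

# reorient to counter-clockwise (positive signed area)
ring_ccw <- function(ring) {
  if (ring_area_signed(ring) < 0) ring[rev(seq_len(nrow(ring))), , drop = FALSE] else ring
}

ring_centroid <- function(ring) {
  x <- ring[, 1L]; y <- ring[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(ring))
  c(sum((x + xn) * cr) / (6 * a), sum((y + yn) * cr) / (6 * a))
}

ring_is_convex <- function(ring) {
  n <- nrow(ring)
  if (n < 4L) return(TRUE)
  p <- ring
  q <- ring[c(2:n, 1L), , drop = FALSE]
  r <- ring[c(3:n, 1L, 2L), , drop = FALSE]
  cr <- (q[, 1L] - p[, 1L]) * (r[, 2L] - q[, 2L]) -
    (q[, 2L] - p[, 2L]) * (r[, 1L] - q[, 1L])
  all(cr >= -1e-9 * max(abs(cr), 1)) || all(cr <= 1e-9 * max(abs(cr), 1))
}

# O(n^2) proper self-intersection test between non-adjacent edges
ring_self_intersects <- function(ring) {
  n <- nrow(ring)
  if (n < 4L) return(FALSE)
  a <- ring
  b <- ring[c(2:n, 1L), , drop = FALSE]
  seg_int <- function(p1, p2, p3, p4) {
    d1 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
    d2 <- (p2[1] - p1[1]) * (p4[2] - p1[2]) - (p2[2] - p1[2]) * (p4[1] - p1[1])
    d3 <- (p4[1] - p3[1]) * (p1[2] - p3[2]) - (p4[2] - p3[2]) * (p1[1] - p3[1])
    d4 <- (p4[1] - p3[1]) * (p2[2] - p3[2]) - (p4[2] - p3[2]) * (p2[1] - p3[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    js <- seq.int(i + 2L, jmax)
    for (j in js) {
      if (seg_int(a[i, ], b[i, ], a[j, ], b[j, ])) return(TRUE)
    }
  }
  FALSE
}

# Sutherland-Hodgman: clip `subject` (any simple ring) against CONVEX
# counter-clockwise ring `clip`. Returns a ring or NULL if empty.
clip_convex <- function(subject, clip) {
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (is.null(out) || nrow(out) < 3L) return(NULL)
    a <- clip[i, ]
    b <- clip[if (i == nc) 1L else i + 1L, ]
    ex <- b[1L] - a[1L]
    ey <- b[2L] - a[2L]
    d <- ex * (out[, 2L] - a[2L]) - ey * (out[, 1L] - a[1L])
    n <- nrow(out)
    nxt <- c(2:n, 1L)
    din <- d >= 0
    d2 <- d[nxt]
    din2 <- din[nxt]
    keep <- matrix(NA_real_, 2L * n, 2L)
    sel <- logical(2L * n)
    cross <- din != din2
    if (any(cross)) {
      t <- d[cross] / (d[cross] - d2[cross])
      p0 <- out[cross, , drop = FALSE]
      p1 <- out[nxt[cross], , drop = FALSE]
      keep[2L * which(cross) - 1L, ] <- p0 + t * (p1 - p0)
      sel[2L * which(cross) - 1L] <- TRUE
    }
    keep[2L * seq_len(n), ] <- out[nxt, , drop = FALSE]
    sel[2L * seq_len(n)] <- din2
    out <- keep[sel, , drop = FALSE]
  }
  if (is.null(out) || nrow(out) < 3L) NULL else out
}

# Intersection area between a polygon (list of rings, holes subtract) and a
# convex CCW clip ring. Uses the smaller-vertex ring as the clipper when both
# are convex, which makes rectangle-vs-256-gon clips cheap.
clip_area_polygon <- function(rings, clip, rings_convex = FALSE) {
  clip_one <- function(ring) {
    ring <- ring_ccw(ring)
    if (rings_convex && nrow(ring) < nrow(clip)) {
      piece <- clip_convex(clip, ring)
    } else {
      piece <- clip_convex(ring, clip)
    }
    if (is.null(piece)) 0 else ring_area(piece)
  }
  a <- clip_one(rings[[1L]])
  if (a == 0 || length(rings) == 1L) return(a)
  a - sum(vapply(rings[-1L], clip_one, numeric(1)))
}

# Regular n-gon approximating a circle, counter-clockwise.
regular_polygon <- function(center, radius, n = 256L) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(center[1L] + radius * cos(th), center[2L] + radius * sin(th))
}

rings_bbox <- function(rings) {
  xs <- unlist(lapply(rings, function(r) r[, 1L]))
  ys <- unlist(lapply(rings, function(r) r[, 2L]))
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}

# Vectorized distances from a point to axis-aligned boxes.
bbox_min_dist <- function(px, py, xmin, ymin, xmax, ymax) {
  dx <- pmax(xmin - px, px - xmax, 0)
  dy <- pmax(ymin - py, py - ymax, 0)
  sqrt(dx^2 + dy^2)
}

bbox_max_dist <- function(px, py, xmin, ymin, xmax, ymax) {
  dx <- pmax(abs(px - xmin), abs(px - xmax))
  dy <- pmax(abs(py - ymin), abs(py - ymax))
  sqrt(dx^2 + dy^2)
}

rect_ring <- function(xmin, ymin, xmax, ymax) {
  cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax))
}
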