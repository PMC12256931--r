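# Plain planar geometry on coordinate matrices (2 columns, metres).
# Polygons are closed or open rings; polyline = ordered vertex matrix.

#' Point-in-polygon test (even-odd rule)
#'
#' @param x,y point coordinates (vectors).
#' @param ring two-column vertex matrix of a single ring (closure optional).
#' @return Logical vector; points exactly on an edge count as inside.
#' @keywords internal
point_in_ring <- function(x, y, ring) {
  ring <- close_ring(ring)
  n <- nrow(ring) - 1L
  inside <- rep(FALSE, length(x))
  on_edge <- rep(FALSE, length(x))
  for (i in seq_len(n)) {
    x1 <- ring[i, 1]; y1 <- ring[i, 2]
    x2 <- ring[i + 1L, 1]; y2 <- ring[i + 1L, 2]
    # crossing test
    crosses <- ((y1 > y) != (y2 > y)) &
      (x < (x2 - x1) * (y - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
    # boundary test
    d <- point_segment_distance(x, y, x1, y1, x2, y2)
    on_edge <- on_edge | d < 1e-9
  }
  inside | on_edge
}

close_ring <- function(ring) {
  if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  ring
}

# Distance from points (x, y) to segment (x1,y1)-(x2,y2); all vectorized in
# the points.
point_segment_distance <- function(x, y, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return(sqrt((x - x1)^2 + (y - y1)^2))
  t <- pmin(1, pmax(0, ((x - x1) * dx + (y - y1) * dy) / len2))
  sqrt((x - (x1 + t * dx))^2 + (y - (y1 + t * dy))^2)
}

# Distance from points to a polygon (0 inside or on the boundary).
point_polygon_distance <- function(x, y, ring) {
  ring <- close_ring(ring)
  d <- rep(Inf, length(x))
  for (i in seq_len(nrow(ring) - 1L)) {
    d <- pmin(d, point_segment_distance(x, y, ring[i, 1], ring[i, 2],
                                        ring[i + 1L, 1], ring[i + 1L, 2]))
  }
  d[point_in_ring(x, y, ring)] <- 0
  d
}

#' Point along a polyline at a given arc length
#'
#' Walks the vertex sequence accumulating segment lengths and linearly
#' interpolates inside the segment containing the target distance.
#'
#' @param coords two-column vertex matrix.
#' @param s target arc length from the first vertex (clamped to the line).
#' @return Length-2 numeric vector (x, y).
#' @keywords internal
point_at_arclength <- function(coords, s) {
  seg <- sqrt(rowSums(diff(coords)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  s <- min(max(s, 0), total)
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- min(i, length(seg))
  if (seg[i] == 0) return(coords[i, ])
  f <- (s - cum[i]) / seg[i]
  coords[i, ] + f * (coords[i + 1L, ] - coords[i, ])
}

# Split a segment at its crossings with polygon edges and report the length
# inside the union of rings (even-odd within ring, inside-any across rings).
segment_length_inside <- function(p1, p2, rings) {
  len <- sqrt(sum((p2 - p1)^2))
  if (len == 0) return(0)
  ts <- c(0, 1)
  for (ring in rings) {
    ring <- close_ring(ring)
    for (i in seq_len(nrow(ring) - 1L)) {
      t <- segment_intersection_param(p1, p2, ring[i, ], ring[i + 1L, ])
      if (!is.na(t)) ts <- c(ts, t)
    }
  }
  ts <- sort(unique(pmin(1, pmax(0, ts))))
  inside_len <- 0
  for (k in seq_len(length(ts) - 1L)) {
    tm <- (ts[k] + ts[k + 1L]) / 2
    mid <- p1 + tm * (p2 - p1)
    if (any(vapply(rings, function(r) point_in_ring(mid[1], mid[2], r), TRUE)))
      inside_len <- inside_len + (ts[k + 1L] - ts[k]) * len
  }
  inside_len
}

# Parameter t in [0,1] where segment a1-a2 crosses segment b1-b2 (NA if none).
segment_intersection_param <- function(a1, a2, b1, b2) {
  r <- a2 - a1; s <- b2 - b1
  denom <- r[1] * s[2] - r[2] * s[1]
  if (abs(denom) < 1e-12) return(NA_real_)
  q <- b1 - a1
  t <- (q[1] * s[2] - q[2] * s[1]) / denom
  u <- (q[1] * r[2] - q[2] * r[1]) / denom
  if (t < -1e-12 || t > 1 + 1e-12 || u < -1e-12 || u > 1 + 1e-12) return(NA_real_)
  t
}
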