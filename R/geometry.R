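# Internal planar-geometry helpers. All coordinates are nm in image
# convention (origin top-left, y increasing downward); polygons are stored
# open (first vertex != last, closure implied) and may wind either way.

# signed area by the shoelace formula; abs() gives the area
polygon_signed_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1L))
  0.5 * sum(x[j] * y - x * y[j])
}

polygon_area <- function(x, y) abs(polygon_signed_area(x, y))

polygon_perimeter <- function(x, y) {
  j <- c(seq_len(length(x))[-1], 1L)
  sum(sqrt((x[j] - x)^2 + (y[j] - y)^2))
}

polygon_centroid <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  cr <- x[j] * y - x * y[j]
  a <- 0.5 * sum(cr)
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((x[j] + x) * cr), sum((y[j] + y) * cr)) / (6 * a)
}

# vectorized even-odd (ray crossing) point-in-polygon test
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses & !is.na(crosses))
    j <- i
  }
  inside
}

# minimum distance from each point to the polygon boundary (edges)
points_dist_to_boundary <- function(px, py, vx, vy) {
  n <- length(vx)
  j <- c(seq_len(n)[-1], 1L)
  best <- rep(Inf, length(px))
  for (i in seq_len(n)) {
    ax <- vx[i]; ay <- vy[i]
    bx <- vx[j[i]]; by <- vy[j[i]]
    dx <- bx - ax; dy <- by - ay
    len2 <- dx * dx + dy * dy
    if (len2 == 0) {
      d <- sqrt((px - ax)^2 + (py - ay)^2)
    } else {
      t <- pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / len2))
      d <- sqrt((px - ax - t * dx)^2 + (py - ay - t * dy)^2)
    }
    best <- pmin(best, d)
  }
  best
}

# signed depth: positive inside, negative outside
points_containment_depth <- function(px, py, vx, vy) {
  d <- points_dist_to_boundary(px, py, vx, vy)
  ifelse(points_in_polygon(px, py, vx, vy), d, -d)
}

# proper segment-intersection test for non-adjacent edge pairs
segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(a, b, c) {
    min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  }
  (d1 == 0 && on_seg(p3, p4, p1)) || (d2 == 0 && on_seg(p3, p4, p2)) ||
    (d3 == 0 && on_seg(p1, p2, p3)) || (d4 == 0 && on_seg(p1, p2, p4))
}

# simplicity check: no two non-adjacent edges intersect; O(n^2), fine for
# the <= 200-vertex outlines this package produces
polygon_is_simple <- function(x, y) {
  n <- length(x)
  if (n < 3) return(FALSE)
  j <- c(seq_len(n)[-1], 1L)
  for (a in seq_len(n - 1L)) {
    for (b in seq((a + 1L), n)) {
      if (b == a || j[b] == a || j[a] == b) next   # adjacent edges share a vertex
      if (segments_intersect(c(x[a], y[a]), c(x[j[a]], y[j[a]]),
                             c(x[b], y[b]), c(x[j[b]], y[j[b]]))) {
        return(FALSE)
      }
    }
  }
  TRUE
}

# resample an open polyline at m points equally spaced in arc length
resample_polyline <- function(x, y, m) {
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total == 0) return(cbind(x = rep(x[1], m), y = rep(y[1], m)))
  t <- seq(0, total, length.out = m)
  cbind(x = stats::approx(s, x, xout = t, ties = "ordered")$y,
        y = stats::approx(s, y, xout = t, ties = "ordered")$y)
}

# resample a closed polygon at m points equally spaced along its perimeter
resample_closed <- function(x, y, m) {
  xs <- c(x, x[1]); ys <- c(y, y[1])
  p <- resample_polyline(xs, ys, m + 1L)
  p[seq_len(m), , drop = FALSE]
}

# circular 3-point moving average for closed contours
smooth_closed <- function(x, y, passes = 1L) {
  for (k in seq_len(passes)) {
    n <- length(x)
    im <- c(n, seq_len(n - 1L)); ip <- c(seq_len(n)[-1], 1L)
    x <- (x[im] + x + x[ip]) / 3
    y <- (y[im] + y + y[ip]) / 3
  }
  cbind(x = x, y = y)
}

# wrap angles into (-pi, pi]
wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  ifelse(w == -pi, pi, w)
}

# minimum vertex-to-edge distance between two polygons (0 if touching);
# callers should test containment/overlap separately
polygon_gap <- function(x1, y1, x2, y2) {
  min(min(points_dist_to_boundary(x1, y1, x2, y2)),
      min(points_dist_to_boundary(x2, y2, x1, y1)))
}
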