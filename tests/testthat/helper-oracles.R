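# Independent oracles and fixture builders shared across the suite.

# scalar even-odd ray-crossing point-in-polygon test, written as the
# plain textbook loop so it stays independent of the package internals
oracle_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((vy[i] > py) != (vy[j] > py)) {
      xint <- (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i]
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# dense-sampling nearest-arc-point projection oracle: samples the arc at
# n_dense points, finds the nearest sample to each query point, reads s
# off the sample index and d off the distance with a radial sign
oracle_project_arc <- function(model, pts, n_dense = 1e5) {
  phi <- seq(model$phi_a, model$phi_a + model$sweep, length.out = n_dense)
  ax <- model$center_nm[1] + model$radius_nm * cos(phi)
  ay <- model$center_nm[2] + model$radius_nm * sin(phi)
  s <- d <- numeric(nrow(pts))
  for (k in seq_len(nrow(pts))) {
    dd <- (ax - pts[k, 1])^2 + (ay - pts[k, 2])^2
    i <- which.min(dd)
    s[k] <- (i - 1) / (n_dense - 1) - 0.5
    r <- sqrt((pts[k, 1] - model$center_nm[1])^2 +
              (pts[k, 2] - model$center_nm[2])^2)
    d[k] <- sqrt(dd[i]) * sign(r - model$radius_nm)
  }
  list(s = s, d = d)
}

# one ground-truth cell row with explicit geometry
make_gt_cell <- function(radius_nm = 2000, length_nm = 2000, width_nm = 600,
                         center = c(10000, 10000), phi_mid = 0,
                         principle_pole = "a", cell_id = 1L) {
  sweep <- length_nm / radius_nm
  tibble::tibble(
    cell_id = cell_id,
    center_x_nm = center[1], center_y_nm = center[2],
    radius_nm = radius_nm,
    phi_a = phi_mid - sweep / 2, phi_b = phi_mid + sweep / 2,
    length_nm = length_nm, width_nm = width_nm,
    principle_pole = principle_pole)
}

# outline tibble of a ground-truth cell (uses the package generator's
# own polygon construction)
gt_outline_tbl <- function(cell, field_id = "F1") {
  p <- arcell:::gt_outline_polygon(cell)
  tibble::tibble(cell_id = cell$cell_id, x_nm = p[, 1], y_nm = p[, 2])
}

# random convex polygon around a center
random_convex_polygon <- function(cx, cy, r_max, n = 12L) {
  ang <- sort(stats::runif(n, 0, 2 * pi))
  r <- stats::runif(n, 0.5 * r_max, r_max)
  tibble::tibble(x_nm = cx + r * cos(ang), y_nm = cy + r * sin(ang))
}

# uniform points inside a polygon (rejection sampling)
runif_in_polygon <- function(n, vx, vy) {
  out <- matrix(NA_real_, 0, 2)
  while (nrow(out) < n) {
    p <- cbind(stats::runif(2 * n, min(vx), max(vx)),
               stats::runif(2 * n, min(vy), max(vy)))
    keep <- vapply(seq_len(nrow(p)),
                   function(i) oracle_in_polygon(p[i, 1], p[i, 2], vx, vy),
                   logical(1))
    out <- rbind(out, p[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

# fixed-radius neighbour-counting cluster oracle: spots are groups of
# points with many close neighbours, linked by single-linkage at r_link
oracle_spot_centers <- function(x, y, r_count = 90, min_nb = 10) {
  n <- length(x)
  d <- as.matrix(stats::dist(cbind(x, y)))
  dense <- colSums(d <= r_count) - 1 >= min_nb
  idx <- which(dense)
  if (!length(idx)) return(NULL)
  g <- igraph::graph_from_adjacency_matrix(
    d[idx, idx, drop = FALSE] <= r_count, mode = "undirected", diag = FALSE)
  comp <- igraph::components(g)$membership
  t(vapply(unique(comp), function(k) {
    c(mean(x[idx[comp == k]]), mean(y[idx[comp == k]]), sum(comp == k))
  }, numeric(3)))
}
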