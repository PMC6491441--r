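test_that("exact circular centerlines are recovered with closed-form arc length", {
  phi <- seq(80, 120, length.out = 21) * pi / 180
  cl <- cbind(3000 + 2000 * cos(phi), 3000 + 2000 * sin(phi))
  fit <- fit_arc(cl)
  expect_equal(fit$kind, "arc")
  expect_equal(fit$radius_nm, 2000, tolerance = 1e-6)
  expect_equal(fit$length_nm, 2000 * (40 * pi / 180), tolerance = 1e-6)
  expect_lt(fit$rmse_nm, 1e-6)
})

test_that("collinear centerlines fall back to a straight fit with chord length", {
  t <- seq(0, 1, length.out = 21)
  cl <- cbind(100 + 1600 * t, 200 + 1200 * t)   # span exactly 2000 nm
  fit <- fit_arc(cl)
  expect_equal(fit$kind, "straight")
  expect_equal(fit$length_nm, 2000, tolerance = 1e-6)
  expect_error(fit_arc(cl[1:4, ]), "at least 5")
})

test_that("arc length is recovered within 3% under 20 nm centerline noise", {
  R <- 2000; L <- 2500
  ok <- 0L
  for (s in 1:30) {
    set.seed(s)
    phi <- seq(-L / (2 * R), L / (2 * R), length.out = 21) + 0.4
    cl <- cbind(5000 + R * cos(phi), 5000 + R * sin(phi)) +
      matrix(rnorm(42, 0, 20), 21, 2)
    fit <- fit_arc(cl)
    if (abs(fit$length_nm - L) / L < 0.03) ok <- ok + 1L
  }
  expect_gte(ok, 29L)
})

test_that("tidy() and glance() summarise arc models broom-style", {
  phi <- seq(0, 1, length.out = 21)
  fit <- fit_arc(cbind(2000 * cos(phi), 2000 * sin(phi)))
  td <- tidy(fit)
  expect_true(all(c("term", "estimate") %in% names(td)))
  expect_equal(td$estimate[td$term == "radius_nm"], 2000, tolerance = 1e-6)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$kind, "arc")
  expect_equal(gl$n, 21L)
})

test_that("frame projection matches geometry at the arc midpoint and outer side", {
  phi <- seq(-0.5, 0.5, length.out = 21) + 1.1
  fit <- fit_arc(cbind(4000 + 2000 * cos(phi), 4000 + 2000 * sin(phi)))
  mid <- phi[11]
  on_arc <- cbind(4000 + 2000 * cos(mid), 4000 + 2000 * sin(mid))
  p <- project_to_cell_frame(fit, on_arc)
  expect_equal(p$s_raw, 0, tolerance = 1e-9)
  expect_equal(p$d_nm, 0, tolerance = 1e-6)
  out30 <- cbind(4000 + 2030 * cos(mid), 4000 + 2030 * sin(mid))
  p2 <- project_to_cell_frame(fit, out30)
  expect_equal(p2$d_nm, 30, tolerance = 1e-6)
  expect_false(p2$clamped)
  # beyond-pole points clamp but keep their radial offset
  beyond <- cbind(4000 + 2010 * cos(phi[1] - 0.2), 4000 + 2010 * sin(phi[1] - 0.2))
  p3 <- project_to_cell_frame(fit, beyond)
  expect_true(p3$clamped)
  expect_equal(abs(p3$s_raw), 0.5)
  expect_equal(p3$d_nm, 10, tolerance = 1e-6)
})

test_that("projection agrees with the dense-sampling nearest-arc-point oracle", {
  set.seed(23)
  phi <- seq(-0.6, 0.65, length.out = 31) + 2.2
  fit <- fit_arc(cbind(8000 + 2000 * cos(phi), 8000 + 2000 * sin(phi)))
  # random points within the sweep, 10-400 nm off the arc on both sides
  u <- runif(300, -0.49, 0.49)
  ang <- fit$phi_a + (u + 0.5) * fit$sweep
  off <- sample(c(-1, 1), 300, TRUE) * runif(300, 10, 400)
  pts <- cbind(8000 + (2000 + off) * cos(ang), 8000 + (2000 + off) * sin(ang))
  got <- project_to_cell_frame(fit, pts)
  exp <- oracle_project_arc(fit, pts, n_dense = 1e5)
  # the oracle's s runs a -> b by sample index; align its sign
  s_or <- if (cor(got$s_raw, exp$s) < 0) -exp$s else exp$s
  expect_lt(max(abs(got$s_raw - s_or)), 1e-3)
  expect_lt(max(abs(got$d_nm - exp$d)), 1e-3)
})

test_that("straight-model projection uses axis position and signed left offset", {
  cl <- cbind(seq(1000, 3000, length.out = 21), rep(500, 21))
  fit <- fit_arc(cl)
  p <- project_to_cell_frame(fit, cbind(c(2000, 1000, 3500), c(400, 500, 560)))
  expect_equal(p$s_raw, c(0, -0.5, 0.5))
  expect_equal(p$clamped, c(FALSE, FALSE, TRUE))
  # axis runs +x; left of it (image convention) is -y... sign convention:
  # d = (p - a) . (-uy, ux) with u = (1, 0) gives d = +(py - ay)
  expect_equal(p$d_nm, c(-100, 0, 60), tolerance = 1e-9)
  expect_false(any(p$curvature_defined))
})

test_that("molecule-to-cell assignment honors containment, tolerance and depth", {
  sq <- tibble::tibble(cell_id = 1L,
                       x_nm = c(0, 1000, 1000, 0), y_nm = c(0, 0, 1000, 1000))
  center <- tibble::tibble(x_nm = 500, y_nm = 500, channel = "t")
  expect_equal(assign_molecules(center, sq)$cell_id, 1L)
  just_out <- tibble::tibble(x_nm = 1005, y_nm = 500, channel = "t")
  expect_equal(assign_molecules(just_out, sq, edge_tolerance_nm = 10)$cell_id, 1L)
  expect_true(is.na(assign_molecules(just_out, sq, edge_tolerance_nm = 1)$cell_id))
})

test_that("assignment matches the brute-force even-odd oracle on random fields", {
  set.seed(17)
  polys <- dplyr::bind_rows(lapply(1:10, function(i) {
    cx <- ((i - 1) %% 5) * 4000 + 2000
    cy <- ((i - 1) %/% 5) * 4000 + 2000
    p <- random_convex_polygon(cx, cy, 1500)
    tibble::tibble(cell_id = i, x_nm = p$x_nm, y_nm = p$y_nm)
  }))
  mols <- tibble::tibble(x_nm = runif(1000, 0, 20000),
                         y_nm = runif(1000, 0, 8000), channel = "t")
  got <- assign_molecules(mols, polys, edge_tolerance_nm = 0)$cell_id
  want <- vapply(seq_len(nrow(mols)), function(k) {
    hit <- NA_integer_
    for (i in 1:10) {
      v <- polys[polys$cell_id == i, ]
      if (oracle_in_polygon(mols$x_nm[k], mols$y_nm[k], v$x_nm, v$y_nm)) {
        hit <- i
        break
      }
    }
    hit
  }, integer(1))
  expect_identical(got, want)
})

test_that("principle-pole orientation flips, ties and is idempotent", {
  rec <- tibble::tibble(s_norm = c(rep(0.45, 10), rep(-0.45, 2)), channel = "t")
  o1 <- orient_cell(rec, "t")
  expect_true(attr(o1, "flipped"))
  expect_equal(sum(o1$s_norm < 0), 10)
  o2 <- orient_cell(o1, "t")
  expect_false(attr(o2, "flipped"))
  expect_equal(o2$s_norm, o1$s_norm)

  tied <- tibble::tibble(s_norm = c(rep(0.4, 5), rep(-0.4, 5)), channel = "t")
  expect_message(ot <- orient_cell(tied, "t"), "tie")
  expect_true(attr(ot, "orientation_tie"))
  expect_equal(ot$s_norm, tied$s_norm)

  none <- tibble::tibble(s_norm = c(0.2, -0.3), channel = "other")
  expect_warning(on <- orient_cell(none, "t"), "no molecules")
  expect_equal(on$s_norm, none$s_norm)
})

test_that("orientation finds the 80% pole across simulated cells", {
  wrong <- 0L
  for (s in 1:40) {
    f <- generate_field(n_cells = 1, seed = 700 + s)
    cell <- f$cells[1, ]
    mols <- simulate_polar_channel(cell, 200, pole_ratio = 0.8,
                                   cytoplasmic_fraction = 0, seed = 7000 + s)
    res <- suppressMessages(map_cells(mols, f$outlines))
    pop <- res$population
    pp <- if (cell$principle_pole == "a") cell$phi_a else cell$phi_b
    tip <- c(cell$center_x_nm + cell$radius_nm * cos(pp),
             cell$center_y_nm + cell$radius_nm * sin(pp))
    neg <- pop[pop$s_norm < -0.3, ]
    if (nrow(neg) < 50) next
    if (mean(sqrt((neg$x_nm - tip[1])^2 + (neg$y_nm - tip[2])^2)) >
        cell$length_nm / 2) {
      wrong <- wrong + 1L
    }
  }
  expect_equal(wrong, 0L)
})

test_that("pooling counts, orders deterministically and rejects duplicate keys", {
  set.seed(2)
  recs <- tidyr::expand_grid(field_id = c("F1", "F2"), cell_id = 1:3,
                             mol_id = 1:10) %>%
    dplyr::mutate(channel = "t", x_nm = runif(60), y_nm = runif(60),
                  s_norm = runif(60, -0.5, 0.5), d_nm = rnorm(60, 0, 50),
                  clamped = FALSE, curvature_defined = TRUE)
  cells <- tidyr::expand_grid(field_id = c("F1", "F2"), cell_id = 1:3) %>%
    dplyr::mutate(length_nm = 2000, rmse_nm = 3)
  pop <- pool_population(recs, cells)
  expect_equal(nrow(pop), 60L)
  expect_equal(nrow(dplyr::distinct(pop, field_id, cell_id)), 6L)
  # permutation invariance
  shuf <- recs[sample.int(60), ]
  pop2 <- pool_population(shuf, cells)
  expect_equal(pop2, pop)
  # empty input
  expect_equal(nrow(pool_population(tibble::tibble(), cells)), 0L)
  # duplicate keys
  expect_error(pool_population(recs, dplyr::bind_rows(cells, cells[1, ])),
               "duplicate")
})
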