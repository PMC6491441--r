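test_that("field generation is deterministic and respects placement rules", {
  f1 <- generate_field(n_cells = 6, seed = 77)
  f2 <- generate_field(n_cells = 6, seed = 77)
  expect_equal(f1$cells, f2$cells)
  expect_equal(f1$outlines, f2$outlines)
  f3 <- generate_field(n_cells = 6, seed = 78)
  expect_false(isTRUE(all.equal(f1$cells, f3$cells)))

  one <- generate_field(n_cells = 1, seed = 3)
  expect_equal(nrow(one$cells), 1L)
  expect_true(all(one$outlines$x_nm > 0 & one$outlines$x_nm < 40960))
  expect_true(all(one$outlines$y_nm > 0 & one$outlines$y_nm < 40960))
})

test_that("a 15-cell field has pairwise disjoint outlines", {
  f <- generate_field(n_cells = 15, seed = 19)
  expect_equal(nrow(f$cells), 15L)
  polys <- lapply(1:15, function(i) f$outlines[f$outlines$cell_id == i, ])
  for (i in 1:14) {
    for (j in (i + 1):15) {
      inter <- polyclip::polyclip(
        list(x = polys[[i]]$x_nm, y = polys[[i]]$y_nm),
        list(x = polys[[j]]$x_nm, y = polys[[j]]$y_nm), "intersection")
      expect_length(inter, 0)
    }
  }
})

test_that("boundary channels sit at the prescribed radial distance", {
  cell <- make_gt_cell()
  exact <- simulate_boundary_channel(cell, 800, radial_offset_nm = 0,
                                     sigma_loc_nm = 0, seed = 5)
  # noise-free membrane emitters: distance to midline == width/2 everywhere
  r <- sqrt((exact$x_nm - cell$center_x_nm)^2 + (exact$y_nm - cell$center_y_nm)^2)
  phi <- atan2(exact$y_nm - cell$center_y_nm, exact$x_nm - cell$center_x_nm)
  in_sweep <- phi >= cell$phi_a & phi <= cell$phi_b
  expect_equal(abs(r[in_sweep] - cell$radius_nm),
               rep(300, sum(in_sweep)), tolerance = 1e-9)

  # empirical |d| spread matches the localization sigma within 10%
  noisy <- simulate_boundary_channel(cell, 3000, 0, sigma_loc_nm = 15, seed = 6)
  rn <- sqrt((noisy$x_nm - cell$center_x_nm)^2 + (noisy$y_nm - cell$center_y_nm)^2)
  phin <- atan2(noisy$y_nm - cell$center_y_nm, noisy$x_nm - cell$center_x_nm)
  sel <- phin >= cell$phi_a & phin <= cell$phi_b
  d <- abs(rn[sel] - cell$radius_nm) - 300
  expect_lt(abs(sd(d) - 15) / 15, 0.10)

  expect_equal(nrow(simulate_boundary_channel(cell, 0)), 0L)
  same1 <- simulate_boundary_channel(cell, 50, seed = 9)
  same2 <- simulate_boundary_channel(cell, 50, seed = 9)
  expect_equal(same1, same2)
})

test_that("two offset boundary channels reproduce their 30 nm separation exactly", {
  cell <- make_gt_cell()
  mesh <- mesh_from_outline(gt_outline_tbl(cell))
  model <- arcell:::fit_cell_arc(mesh)
  mk <- function(off, seed) {
    ch <- simulate_boundary_channel(cell, 2000, off, sigma_loc_nm = 0, seed = seed)
    pr <- project_to_cell_frame(model, ch)
    tibble::tibble(field_id = "F1", cell_id = 1L, channel = "x",
                   mol_id = seq_len(nrow(ch)), x_nm = ch$x_nm, y_nm = ch$y_nm,
                   s_norm = pr$s_raw, d_nm = pr$d_nm, clamped = pr$clamped,
                   curvature_defined = pr$curvature_defined)
  }
  off <- radial_offset(mk(0, 1), mk(30, 2))
  expect_equal(off$offset_nm, 30, tolerance = 0.5)
})

test_that("polar channels respect pole ratio, cytoplasmic pool and side bias", {
  cell <- make_gt_cell(principle_pole = "b")
  tips <- rbind(
    a = c(cell$center_x_nm + cell$radius_nm * cos(cell$phi_a),
          cell$center_y_nm + cell$radius_nm * sin(cell$phi_a)),
    b = c(cell$center_x_nm + cell$radius_nm * cos(cell$phi_b),
          cell$center_y_nm + cell$radius_nm * sin(cell$phi_b)))
  mono <- simulate_polar_channel(cell, 300, pole_ratio = 1,
                                 polar_sigma_nm = 100,
                                 cytoplasmic_fraction = 0, seed = 4)
  d_pp <- sqrt((mono$x_nm - tips["b", 1])^2 + (mono$y_nm - tips["b", 2])^2)
  expect_true(all(d_pp < 3.5 * 100 + 300))
  expect_true(all(mono$true_pole == "principle"))

  set.seed(1)
  unbiased <- simulate_polar_channel(cell, 4000, side_bias = 0.5, seed = 10)
  d_true <- sqrt((unbiased$x_nm - cell$center_x_nm)^2 +
                 (unbiased$y_nm - cell$center_y_nm)^2) - cell$radius_nm
  expect_lt(abs(mean(d_true < 0) - 0.5), 1.96 * sqrt(0.25 / 4000) + 0.01)

  biased <- simulate_polar_channel(cell, 4000, side_bias = 0.7, seed = 11)
  d_b <- sqrt((biased$x_nm - cell$center_x_nm)^2 +
              (biased$y_nm - cell$center_y_nm)^2) - cell$radius_nm
  expect_lt(abs(mean(d_b < 0) - 0.7), 1.96 * sqrt(0.21 / 4000) + 0.01)

  # all molecules land inside the outline
  poly <- gt_outline_tbl(cell)
  inside <- vapply(seq_len(nrow(biased)), function(i)
    oracle_in_polygon(biased$x_nm[i], biased$y_nm[i], poly$x_nm, poly$y_nm),
    logical(1))
  expect_gte(mean(inside), 0.999)
})

test_that("ground truth exports round-trip with full molecule coverage", {
  f <- generate_field(n_cells = 4, seed = 55)
  mols <- dplyr::bind_rows(lapply(1:4, function(i) {
    m <- simulate_polar_channel(f$cells[i, ], 30, seed = 550 + i)
    m$cell_id <- i
    m
  }))
  dir <- withr::local_tempdir()
  export_ground_truth(f, dir, molecules = mols)
  back <- read_ground_truth(dir)
  expect_equal(back$cells$radius_nm, f$cells$radius_nm, tolerance = 1e-9)
  expect_equal(back$cells$principle_pole, f$cells$principle_pole)
  expect_equal(nrow(back$outlines), nrow(f$outlines))
  expect_equal(back$outlines$x_nm, f$outlines$x_nm, tolerance = 1e-6)
  expect_equal(nrow(back$molecules), 120L)
  expect_setequal(unique(back$molecules$cell_id), 1:4)

  # empty field export: header-only molecule table is not written,
  # outlines file still round-trips
  f0 <- generate_field(n_cells = 1, seed = 2)
  d2 <- withr::local_tempdir()
  export_ground_truth(f0, d2)
  expect_true(file.exists(file.path(d2, "outlines.txt")))
  expect_null(read_ground_truth(d2)$molecules)
})
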