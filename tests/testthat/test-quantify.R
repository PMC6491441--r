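pop_of <- function(s, d = NULL, curved = TRUE) {
  n <- length(s)
  tibble::tibble(field_id = "F1", cell_id = 1L, channel = "t", mol_id = seq_len(n),
                 x_nm = 0, y_nm = 0, s_norm = s,
                 d_nm = if (is.null(d)) rep(0, n) else d,
                 clamped = FALSE, curvature_defined = curved)
}

test_that("zone fractions follow their definitions and sum to one", {
  zs <- zone_fractions(pop_of(rep(-0.5, 20)))
  expect_equal(zs$frac_polar_principle, 1)

  set.seed(8)
  s <- runif(1e4, -0.5, 0.5)
  zs2 <- zone_fractions(pop_of(s, d = rnorm(1e4)), polar_cutoff = 0.4)
  expect_equal(zs2$frac_polar_principle, 0.1, tolerance = 0.12)
  expect_equal(zs2$frac_polar_secondary, 0.1, tolerance = 0.12)
  expect_equal(zs2$frac_middle, 0.8, tolerance = 0.03)
  expect_equal(zs2$frac_polar_principle + zs2$frac_polar_secondary +
                 zs2$frac_middle, 1, tolerance = 1e-9)
  expect_equal(zs2$frac_outer + zs2$frac_inner, 1, tolerance = 1e-9)

  expect_warning(ze <- zone_fractions(pop_of(numeric(0))), "empty")
  expect_true(is.nan(ze$frac_middle))
  expect_error(zone_fractions(pop_of(0), polar_cutoff = 0.6))
})

test_that("zone fractions recover a generated outer-side bias", {
  set.seed(12)
  n <- 4000
  outer <- runif(n) < 0.7
  d <- ifelse(outer, abs(rnorm(n, 150, 80)), -abs(rnorm(n, 150, 80)))
  zs <- zone_fractions(pop_of(runif(n, -0.5, 0.5), d))
  expect_lt(abs(zs$frac_outer - 0.7), 1.96 * sqrt(0.7 * 0.3 / n) + 0.01)
})

test_that("zone fractions are invariant to molecule order", {
  set.seed(13)
  tbl <- pop_of(runif(500, -0.5, 0.5), rnorm(500))
  expect_equal(zone_fractions(tbl[sample.int(500), ]), zone_fractions(tbl))
})

test_that("axial histograms bin [-0.5, 0.5] with closed last bin", {
  h <- axial_histogram(pop_of(-0.5), n_bins = 10)
  expect_equal(h$count[1], 1L)
  h2 <- axial_histogram(pop_of(0.5), n_bins = 10)
  expect_equal(h2$count[10], 1L)

  set.seed(4)
  tbl <- pop_of(runif(1234, -0.5, 0.5))
  h3 <- axial_histogram(tbl, n_bins = 20, normalize = FALSE)
  expect_equal(sum(h3$count), 1234L)
  h4 <- axial_histogram(tbl, n_bins = 20)
  expect_equal(sum(h4$density), 1)

  # uniform s: no bin deviates from 1/n_bins by more than 4 binomial sd
  set.seed(44)
  tbl5 <- pop_of(runif(1e5, -0.5, 0.5))
  h5 <- axial_histogram(tbl5, n_bins = 50)
  sd_bin <- sqrt(0.02 * 0.98 / 1e5)
  expect_lt(max(abs(h5$density - 0.02)), 4 * sd_bin)
})

test_that("radial offset reproduces exact constructions and antisymmetry", {
  cell <- make_gt_cell()
  mesh <- mesh_from_outline(gt_outline_tbl(cell))
  model <- fit_arc(arcell:::mesh_centerline(mesh))
  mk <- function(ch) {
    pr <- project_to_cell_frame(model, ch)
    tibble::tibble(field_id = "F1", cell_id = 1L, channel = "x",
                   mol_id = seq_len(nrow(ch)), x_nm = ch$x_nm, y_nm = ch$y_nm,
                   s_norm = pr$s_raw, d_nm = pr$d_nm, clamped = pr$clamped,
                   curvature_defined = pr$curvature_defined)
  }
  a <- mk(simulate_boundary_channel(cell, 1500, 0, sigma_loc_nm = 0, seed = 1))
  b30 <- mk(simulate_boundary_channel(cell, 1500, 30, sigma_loc_nm = 0, seed = 2))
  expect_equal(radial_offset(a, b30)$offset_nm, 30, tolerance = 0.5)
  expect_equal(radial_offset(a, a)$offset_nm, 0, tolerance = 1e-9)
  expect_equal(radial_offset(a, b30)$offset_nm,
               -radial_offset(b30, a)$offset_nm, tolerance = 1e-9)
  # under-populated cells are excluded and counted
  few <- a[1:10, ]
  expect_warning(r <- radial_offset(few, few), "enough molecules")
  expect_equal(r$n_cells_excluded, 1L)
})

test_that("radial offset is recovered within 5 nm under 15 nm noise", {
  offs <- c()
  for (s in 1:3) {
    f <- generate_field(n_cells = 4, seed = 50 + s, field_nm = 25000)
    pa <- pb <- list()
    for (i in 1:4) {
      cell <- f$cells[i, ]
      mesh <- mesh_from_outline(f$outlines[f$outlines$cell_id == i, ])
      model <- arcell:::fit_cell_arc(mesh)
      mk <- function(ch) {
        pr <- project_to_cell_frame(model, ch)
        tibble::tibble(field_id = "F1", cell_id = i, channel = "x",
                       mol_id = seq_len(nrow(ch)), x_nm = ch$x_nm, y_nm = ch$y_nm,
                       s_norm = pr$s_raw, d_nm = pr$d_nm, clamped = pr$clamped,
                       curvature_defined = pr$curvature_defined)
      }
      pa[[i]] <- mk(simulate_boundary_channel(cell, 3000, 0, 15, seed = s * 20 + i))
      pb[[i]] <- mk(simulate_boundary_channel(cell, 3000, 30, 15, seed = 500 + s * 20 + i))
    }
    offs <- c(offs, radial_offset(dplyr::bind_rows(pa), dplyr::bind_rows(pb))$offset_nm)
  }
  expect_true(all(abs(offs - 30) < 5))
})

test_that("summaries recompute identically from a written-and-reread table", {
  set.seed(21)
  tbl <- pop_of(runif(800, -0.5, 0.5), rnorm(800, 0, 100))
  f <- withr::local_tempfile(fileext = ".csv")
  write_population_table(tbl, f)
  back <- read_population_table(f)
  expect_equal(zone_fractions(back), zone_fractions(tbl), tolerance = 1e-9)
  expect_equal(axial_histogram(back, 25), axial_histogram(tbl, 25))
})
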