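test_that("pixel binning follows the half-open convention and reconstruction-scale geometry", {
  one <- tibble::tibble(x_nm = 16, y_nm = 16)
  img <- render_localization_image(one, pixel_nm = 32,
                                   extent_nm = c(40960, 40960))
  expect_equal(dim(img$counts), c(1280L, 1280L))
  expect_equal(img$counts[1, 1], 1)
  expect_equal(sum(img$counts), 1)

  # boundary molecule at exactly 32 nm goes to the second pixel
  img2 <- render_localization_image(tibble::tibble(x_nm = 32, y_nm = 0),
                                    pixel_nm = 32, extent_nm = c(128, 128))
  expect_equal(img2$counts[2, 1], 1)
})

test_that("counts mode conserves the number of in-field molecules at any pixel size", {
  set.seed(5)
  mols <- tibble::tibble(x_nm = runif(500, 0, 5000), y_nm = runif(500, 0, 5000))
  for (px in c(20, 32, 64)) {
    img <- render_localization_image(mols, px, extent_nm = c(5000, 5000))
    expect_equal(sum(img$counts), 500)
  }
  # halving the pixel size doubles grid dimensions (camera-style field
  # extents are whole multiples of the pixel size)
  mols4 <- dplyr::filter(mols, x_nm < 4096, y_nm < 4096)
  i1 <- render_localization_image(mols4, 32, extent_nm = c(4096, 4096))
  i2 <- render_localization_image(mols4, 16, extent_nm = c(4096, 4096))
  expect_equal(dim(i2$counts), 2L * dim(i1$counts))
  # out-of-field molecules are dropped with a warning
  expect_warning(
    i3 <- render_localization_image(
      tibble::tibble(x_nm = c(10, 6000), y_nm = c(10, 10)), 32,
      extent_nm = c(5000, 5000)),
    "outside")
  expect_equal(sum(i3$counts), 1)
})

test_that("gaussian rendering deposits unit mass per molecule", {
  mols <- tibble::tibble(x_nm = c(500, 1200), y_nm = c(700, 300))
  img <- render_localization_image(mols, 32, mode = "gaussian", sigma_nm = 20,
                                   extent_nm = c(2000, 2000))
  expect_equal(sum(img$counts), 2, tolerance = 1e-9)
})

test_that("fixed-threshold binarization keeps exactly the dense band", {
  counts <- matrix(0, 64, 64)
  counts[10:19, 10:49] <- 5
  img <- structure(list(counts = counts, pixel_nm = 32, origin_nm = c(0, 0),
                        extent_nm = c(2048, 2048), n_rendered = sum(counts)),
                   class = "loc_image")
  m <- binarize(img, method = "fixed", threshold = 1, closing_radius_nm = 0)
  expect_equal(m$mask, counts > 0)
})

test_that("an all-zero image binarizes to an all-false mask with a warning", {
  img <- structure(list(counts = matrix(0, 8, 8), pixel_nm = 32,
                        origin_nm = c(0, 0), extent_nm = c(256, 256),
                        n_rendered = 0), class = "loc_image")
  expect_warning(m <- binarize(img), "all-zero")
  expect_false(any(m$mask))
})

test_that("a rendered membrane ring binarizes to a mask near the true cell area", {
  cell <- make_gt_cell(radius_nm = 2000, length_nm = 2500, center = c(5000, 5000))
  ch <- simulate_boundary_channel(cell, 3000, 0, sigma_loc_nm = 15, seed = 9)
  img <- render_localization_image(ch, 32, extent_nm = c(10000, 10000))
  mask <- binarize(img)
  ol <- extract_cell_outlines(mask, border_margin_nm = 100)
  expect_equal(length(unique(ol$cell_id)), 1L)
  truth <- cell$length_nm * cell$width_nm + pi * (cell$width_nm / 2)^2
  got <- arcell:::polygon_area(ol$x_nm, ol$y_nm)
  expect_lt(abs(got - truth) / truth, 0.20)
})

test_that("component filters drop border-touching and out-of-range cells", {
  counts <- matrix(0, 128, 128)
  counts[40:55, 30:92] <- 2      # ~0.5 x 2 um interior rectangle
  counts[1:16, 5:67] <- 2        # same size but touching the border
  img <- structure(list(counts = counts, pixel_nm = 32, origin_nm = c(0, 0),
                        extent_nm = c(4096, 4096), n_rendered = sum(counts)),
                   class = "loc_image")
  mask <- binarize(img, method = "fixed", threshold = 1, closing_radius_nm = 0)
  ol <- extract_cell_outlines(mask, border_margin_nm = 200)
  expect_equal(length(unique(ol$cell_id)), 1L)
  # the kept rectangle has the right area (16 x 63 pixels)
  expect_equal(arcell:::polygon_area(ol$x_nm, ol$y_nm) / 1e6,
               16 * 63 * 32^2 / 1e6, tolerance = 0.15)
  # all outlines respect the vertex budget
  expect_lte(max(table(ol$cell_id)), 200)
})

test_that("every cell of a synthetic field is segmented and contains its own centroid", {
  f <- generate_field(n_cells = 10, seed = 31)
  ch <- dplyr::bind_rows(lapply(seq_len(10), function(i)
    simulate_boundary_channel(f$cells[i, ], 2500, 0, 15, seed = 310 + i)))
  mask <- binarize(render_localization_image(ch, 32))
  ol <- extract_cell_outlines(mask, shrink_nm = 30)
  expect_equal(length(unique(ol$cell_id)), 10L)
  centro <- cbind(f$cells$center_x_nm + f$cells$radius_nm *
                    cos((f$cells$phi_a + f$cells$phi_b) / 2),
                  f$cells$center_y_nm + f$cells$radius_nm *
                    sin((f$cells$phi_a + f$cells$phi_b) / 2))
  hits <- vapply(seq_len(10), function(i) {
    any(vapply(unique(ol$cell_id), function(id) {
      o <- ol[ol$cell_id == id, ]
      oracle_in_polygon(centro[i, 1], centro[i, 2], o$x_nm, o$y_nm)
    }, logical(1)))
  }, logical(1))
  expect_true(all(hits))
})

test_that("meshes recover axis, poles and midline geometry", {
  # dense axis-aligned rectangle: centerline on the long axis, poles at
  # the short ends
  rect <- tibble::tibble(
    cell_id = 1L,
    x_nm = c(seq(0, 500, by = 10), rep(500, 199), seq(500, 0, by = -10), rep(0, 199)),
    y_nm = c(rep(0, 51), seq(10, 1990, by = 10), rep(2000, 51), seq(1990, 10, by = -10)))
  m <- mesh_from_outline(rect, n_ribs = 11)
  expect_lt(max(abs(m$x_mid - 250)), 1)
  expect_setequal(round(c(m$y_mid[1], m$y_mid[11])), c(0, 2000))
  # centerline points are rib midpoints
  expect_equal(m$x_mid, (m$x_left + m$x_right) / 2, tolerance = 1e-9)

  # a circle has no elongation axis
  th <- seq(0, 2 * pi, length.out = 100)[-100]
  circ <- tibble::tibble(cell_id = 1L, x_nm = 1000 + 400 * cos(th),
                         y_nm = 1000 + 400 * sin(th))
  expect_error(mesh_from_outline(circ), "no elongation axis")

  # curved synthetic cell: centerline within 40 nm RMS of the true midline
  cell <- make_gt_cell(radius_nm = 2000, length_nm = 2500, phi_mid = 0.7)
  mesh <- mesh_from_outline(gt_outline_tbl(cell))
  r_mid <- sqrt((mesh$x_mid - cell$center_x_nm)^2 +
                (mesh$y_mid - cell$center_y_nm)^2)
  expect_lt(sqrt(mean((r_mid - cell$radius_nm)^2)), 40)
})

test_that("mirroring an outline mirrors its mesh", {
  cell <- make_gt_cell(radius_nm = 1800, length_nm = 2200, phi_mid = 0.3)
  ol <- gt_outline_tbl(cell)
  m1 <- mesh_from_outline(ol)
  ol2 <- dplyr::mutate(ol, x_nm = -x_nm)
  m2 <- mesh_from_outline(ol2)
  # compare midline point sets after mirroring back (direction may flip)
  a <- cbind(m1$x_mid, m1$y_mid)
  b <- cbind(-m2$x_mid, m2$y_mid)
  d_fwd <- max(sqrt(rowSums((a - b)^2)))
  d_rev <- max(sqrt(rowSums((a - b[rev(seq_len(nrow(b))), ])^2)))
  expect_lt(min(d_fwd, d_rev), 10)
})
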