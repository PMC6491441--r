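# unit vector at angle phi
e_hat <- function(phi) cbind(cos(phi), sin(phi))

# outline polygon of one ground-truth cell: midline arc dilated by
# width/2 with semicircular caps; returns matrix (x, y)
gt_outline_polygon <- function(cell, n_bank = 36L, n_cap = 12L, offset_nm = 0) {
  h <- cell$width_nm / 2 + offset_nm
  R <- cell$radius_nm
  cx <- cell$center_x_nm; cy <- cell$center_y_nm
  pa <- cell$phi_a; pb <- cell$phi_b
  outer_phi <- seq(pa, pb, length.out = n_bank)
  inner_phi <- seq(pb, pa, length.out = n_bank)
  cap_b <- seq(pb, pb + pi, length.out = n_cap + 2L)[2:(n_cap + 1L)]
  cap_a <- seq(pa + pi, pa + 2 * pi, length.out = n_cap + 2L)[2:(n_cap + 1L)]
  m_a <- c(cx, cy) + R * c(cos(pa), sin(pa))
  m_b <- c(cx, cy) + R * c(cos(pb), sin(pb))
  pts <- rbind(
    cbind(cx + (R + h) * cos(outer_phi), cy + (R + h) * sin(outer_phi)),
    cbind(m_b[1] + h * cos(cap_b), m_b[2] + h * sin(cap_b)),
    cbind(cx + (R - h) * cos(inner_phi), cy + (R - h) * sin(inner_phi)),
    cbind(m_a[1] + h * cos(cap_a), m_a[2] + h * sin(cap_a)))
  colnames(pts) <- c("x", "y")
  pts
}

# true midline sampled at m points (pole a -> pole b)
gt_midline <- function(cell, m = 101L) {
  phi <- seq(cell$phi_a, cell$phi_b, length.out = m)
  cbind(x = cell$center_x_nm + cell$radius_nm * cos(phi),
        y = cell$center_y_nm + cell$radius_nm * sin(phi))
}

#' Generate a synthetic field of curved-rod cells
#'
#' Places ground-truth vibrioid cells in a square field. Each cell is a
#' circular-arc midline of random length and curvature radius, dilated
#' by half the cell width with semicircular pole caps; cells are placed
#' at random position and orientation by rejection sampling so that
#' outlines stay at least `clearance_nm` apart and `margin_nm` away from
#' the field edge. One pole per cell is labelled the principle pole.
#' Fully deterministic given `seed`.
#'
#' Defaults emulate a typical PALM acquisition of *V. cholerae*-like
#' cells: a 40960 nm field with ~15 cells of 1-3 um midline length,
#' 600 nm width and 1.5-3 um curvature radius.
#'
#' @param n_cells Number of cells (default 15).
#' @param field_nm Square field side in nm (default 40960).
#' @param length_range Midline arc length range in nm (default
#'   1000-3000).
#' @param width_nm Cell width in nm (default 600).
#' @param curvature_radius_range Arc radius range in nm (default
#'   1500-3000).
#' @param clearance_nm Minimum outline-to-outline distance (default
#'   400).
#' @param margin_nm Minimum outline-to-field-edge distance (default
#'   500).
#' @param seed RNG seed.
#' @param max_attempts Placement attempts before giving up (default
#'   10000).
#' @return Object of class `gt_field`: list with `cells` (tibble:
#'   `cell_id`, `center_x_nm`, `center_y_nm`, `radius_nm`, `phi_a`,
#'   `phi_b`, `length_nm`, `width_nm`, `principle_pole`), `outlines`
#'   (outline tibble), `field_nm`, `seed`. `length_nm` is the midline
#'   arc length; tip-to-tip cell length is `length_nm + width_nm`.
#' @export
generate_field <- function(n_cells = 15L, field_nm = 40960,
                           length_range = c(1000, 3000), width_nm = 600,
                           curvature_radius_range = c(1500, 3000),
                           clearance_nm = 400, margin_nm = 500,
                           seed = 1L, max_attempts = 10000L) {
  stopifnot(n_cells >= 1L, field_nm > 0, all(length_range > 0),
            width_nm > 0, all(curvature_radius_range > 0),
            width_nm < min(length_range))
  withr_seed(seed, {
    cells <- list()
    polys <- list()
    attempts <- 0L
    while (length(cells) < n_cells) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        abort(paste0("generate_field: could not place ", n_cells,
                     " cells in ", max_attempts,
                     " attempts; use fewer or smaller cells"))
      }
      L <- runif(1, length_range[1], length_range[2])
      R <- runif(1, curvature_radius_range[1], curvature_radius_range[2])
      sweep <- L / R
      if (sweep >= pi) next
      phi_mid <- runif(1, 0, 2 * pi)
      pos <- runif(2, 0, field_nm)
      cand <- tibble(
        cell_id = length(cells) + 1L,
        center_x_nm = pos[1] - R * cos(phi_mid),
        center_y_nm = pos[2] - R * sin(phi_mid),
        radius_nm = R,
        phi_a = phi_mid - sweep / 2,
        phi_b = phi_mid + sweep / 2,
        length_nm = L, width_nm = width_nm,
        principle_pole = sample(c("a", "b"), 1))
      poly <- gt_outline_polygon(cand)
      if (min(poly) < margin_nm || max(poly) > field_nm - margin_nm) next
      ok <- TRUE
      for (p in polys) {
        # bounding boxes farther apart than the clearance cannot conflict
        if (min(poly[, 1]) - max(p[, 1]) > clearance_nm ||
            min(p[, 1]) - max(poly[, 1]) > clearance_nm ||
            min(poly[, 2]) - max(p[, 2]) > clearance_nm ||
            min(p[, 2]) - max(poly[, 2]) > clearance_nm) next
        if (any(points_in_polygon(poly[, 1], poly[, 2], p[, 1], p[, 2])) ||
            any(points_in_polygon(p[, 1], p[, 2], poly[, 1], poly[, 2])) ||
            polygon_gap(poly[, 1], poly[, 2], p[, 1], p[, 2]) < clearance_nm) {
          ok <- FALSE
          break
        }
      }
      if (!ok) next
      cells[[length(cells) + 1L]] <- cand
      polys[[length(polys) + 1L]] <- poly
    }
    outlines <- bind_rows(lapply(seq_along(polys), function(i) {
      tibble(cell_id = i, x_nm = polys[[i]][, 1], y_nm = polys[[i]][, 2])
    }))
    structure(list(cells = bind_rows(cells), outlines = outlines,
                   field_nm = field_nm, seed = seed),
              class = "gt_field")
  })
}

#' @export
print.gt_field <- function(x, ...) {
  cat("<gt_field> ", nrow(x$cells), " cells in a ", x$field_nm, " nm field (seed ",
      x$seed, ")\n", sep = "")
  invisible(x)
}

#' Simulate a boundary-tracing channel for one cell
#'
#' Emits localizations of a membrane- or periplasm-marker: emitter true
#' positions are uniform (by arc length) along the closed contour at
#' distance `width/2 + radial_offset_nm` from the midline — offset 0
#' models an inner-membrane (MTS) marker, ~30 nm a periplasmic marker —
#' and observed positions add isotropic Gaussian localization noise.
#' Frames are assigned sequentially.
#'
#' @param cell One row of a `gt_field` `cells` tibble.
#' @param n_molecules Number of localizations.
#' @param radial_offset_nm Offset of the emitter contour from the
#'   membrane midline (default 0).
#' @param sigma_loc_nm Localization precision sigma in nm (default 15).
#' @param seed RNG seed.
#' @param channel Channel label (default `"boundary"`).
#' @return Molecule tibble (`x_nm`, `y_nm`, `frame`, `intensity`,
#'   `precision_nm`, `channel`).
#' @export
simulate_boundary_channel <- function(cell, n_molecules,
                                      radial_offset_nm = 0,
                                      sigma_loc_nm = 15, seed = 1L,
                                      channel = "boundary") {
  stopifnot(n_molecules >= 0)
  if (n_molecules == 0L) {
    return(tibble(x_nm = numeric(), y_nm = numeric(), frame = integer(),
                  intensity = numeric(), precision_nm = numeric(),
                  channel = character()))
  }
  h <- cell$width_nm / 2 + radial_offset_nm
  R <- cell$radius_nm
  sweep <- cell$phi_b - cell$phi_a
  cen <- c(cell$center_x_nm, cell$center_y_nm)
  m_a <- cen + R * c(cos(cell$phi_a), sin(cell$phi_a))
  m_b <- cen + R * c(cos(cell$phi_b), sin(cell$phi_b))
  seg_len <- c(outer = (R + h) * sweep, cap_b = pi * h,
               inner = (R - h) * sweep, cap_a = pi * h)
  withr_seed(seed, {
    u <- runif(n_molecules, 0, sum(seg_len))
    brk <- cumsum(seg_len)
    seg <- findInterval(u, c(0, brk), rightmost.closed = TRUE)
    pos <- matrix(0, n_molecules, 2)
    for (k in seq_len(n_molecules)) {
      w <- u[k] - c(0, brk)[seg[k]]
      pos[k, ] <- switch(seg[k],
        { phi <- cell$phi_a + w / (R + h); cen + (R + h) * c(cos(phi), sin(phi)) },
        { psi <- cell$phi_b + w / h;       m_b + h * c(cos(psi), sin(psi)) },
        { phi <- cell$phi_b - w / (R - h); cen + (R - h) * c(cos(phi), sin(phi)) },
        { psi <- cell$phi_a + pi + w / h;  m_a + h * c(cos(psi), sin(psi)) })
    }
    obs <- pos + matrix(rnorm(2 * n_molecules, 0, sigma_loc_nm), n_molecules, 2)
    tibble(x_nm = obs[, 1], y_nm = obs[, 2], frame = seq_len(n_molecules),
           intensity = 0, precision_nm = sigma_loc_nm, channel = channel)
  })
}

#' Simulate a polar-protein channel for one cell
#'
#' Emits localizations of a polar landmark protein with skewed
#' bipolarity, a cytoplasmic pool and an optional inner-curve bias:
#' a fraction `1 - cytoplasmic_fraction` of molecules is drawn from 2D
#' Gaussians (`polar_sigma_nm`) at the two midline pole tips with
#' proportions `pole_ratio : (1 - pole_ratio)` (the `pole_ratio` share
#' goes to the cell's principle pole); the rest are uniform inside the
#' outline. Each molecule is placed on the inner (concave) side with
#' probability `side_bias`, reflecting it radially across the midline
#' when it starts on the wrong side. All positions are rejection-sampled
#' into the outline polygon.
#'
#' @param cell One row of a `gt_field` `cells` tibble.
#' @param n_molecules Number of localizations.
#' @param pole_ratio Share of polar molecules at the principle pole,
#'   in `[0.5, 1]` (default 0.8).
#' @param polar_sigma_nm Sigma of the polar 2D Gaussians (default 150).
#' @param cytoplasmic_fraction Share of uniformly distributed molecules
#'   (default 0.15).
#' @param side_bias Probability of the inner side (default 0.5 =
#'   unbiased).
#' @param seed RNG seed.
#' @param channel Channel label (default `"target"`).
#' @return Molecule tibble as in [simulate_boundary_channel()], plus a
#'   `true_pole` column (`"principle"`, `"secondary"` or `"cyto"`).
#' @export
simulate_polar_channel <- function(cell, n_molecules, pole_ratio = 0.8,
                                   polar_sigma_nm = 150,
                                   cytoplasmic_fraction = 0.15,
                                   side_bias = 0.5, seed = 1L,
                                   channel = "target") {
  stopifnot(pole_ratio >= 0.5, pole_ratio <= 1,
            cytoplasmic_fraction >= 0, cytoplasmic_fraction <= 1,
            side_bias >= 0, side_bias <= 1)
  if (n_molecules == 0L) {
    return(tibble(x_nm = numeric(), y_nm = numeric(), frame = integer(),
                  intensity = numeric(), precision_nm = numeric(),
                  channel = character(), true_pole = character()))
  }
  poly <- gt_outline_polygon(cell)
  R <- cell$radius_nm
  cen <- c(cell$center_x_nm, cell$center_y_nm)
  tip_a <- cen + R * c(cos(cell$phi_a), sin(cell$phi_a))
  tip_b <- cen + R * c(cos(cell$phi_b), sin(cell$phi_b))
  if (cell$principle_pole == "a") {
    tips <- rbind(principle = tip_a, secondary = tip_b)
  } else {
    tips <- rbind(principle = tip_b, secondary = tip_a)
  }
  bbox <- c(range(poly[, 1]), range(poly[, 2]))

  withr_seed(seed, {
    cat_draw <- runif(n_molecules)
    category <- ifelse(cat_draw < cytoplasmic_fraction, "cyto",
                       ifelse(runif(n_molecules) < pole_ratio,
                              "principle", "secondary"))
    want_inner <- runif(n_molecules) < side_bias
    x <- numeric(n_molecules); y <- numeric(n_molecules)
    for (k in seq_len(n_molecules)) {
      for (try in seq_len(200L)) {
        if (category[k] == "cyto") {
          p <- c(runif(1, bbox[1], bbox[2]), runif(1, bbox[3], bbox[4]))
          if (!points_in_polygon(p[1], p[2], poly[, 1], poly[, 2])) next
        } else {
          p <- tips[category[k], ] + rnorm(2, 0, polar_sigma_nm)
        }
        r <- sqrt(sum((p - cen)^2))
        is_inner <- r < R
        if (is_inner != want_inner[k]) {
          # radial reflection across the midline circle
          p <- cen + (p - cen) * (2 * R - r) / r
        }
        if (points_in_polygon(p[1], p[2], poly[, 1], poly[, 2])) {
          x[k] <- p[1]; y[k] <- p[2]
          break
        }
        if (try == 200L) { x[k] <- p[1]; y[k] <- p[2] }
      }
    }
    tibble(x_nm = x, y_nm = y, frame = seq_len(n_molecules),
           intensity = 0, precision_nm = NA_real_, channel = channel,
           true_pole = category)
  })
}

#' Export ground truth for a synthetic field
#'
#' Writes the true outlines (outline text format), the midline
#' parameters (TSV) and, optionally, per-molecule true cell assignments
#' (CSV) so that oracle tests can compare pipeline output against the
#' generator.
#'
#' @param field A `gt_field`.
#' @param dir Output directory (created if needed).
#' @param molecules Optional molecule tibble with a `cell_id` column of
#'   true assignments.
#' @return `dir`, invisibly. Files: `outlines.txt`, `cells.tsv`,
#'   `molecules.csv` (if given).
#' @seealso [read_ground_truth()]
#' @export
export_ground_truth <- function(field, dir, molecules = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_outline_set(field$outlines, file.path(dir, "outlines.txt"))
  cells <- field$cells
  cells$field_nm <- field$field_nm
  readr::write_tsv(cells, file.path(dir, "cells.tsv"), progress = FALSE)
  if (!is.null(molecules)) {
    readr::write_csv(molecules, file.path(dir, "molecules.csv"), progress = FALSE)
  }
  invisible(dir)
}

#' Read back an exported ground truth
#'
#' @param dir Directory written by [export_ground_truth()].
#' @return A `gt_field` (plus `molecules` element when present).
#' @export
read_ground_truth <- function(dir) {
  cells <- readr::read_tsv(file.path(dir, "cells.tsv"), show_col_types = FALSE,
                           progress = FALSE)
  field_nm <- if ("field_nm" %in% names(cells)) cells$field_nm[1] else NA_real_
  cells$field_nm <- NULL
  out <- structure(list(
    cells = as_tibble(cells),
    outlines = read_outline_set(file.path(dir, "outlines.txt")),
    field_nm = field_nm, seed = NA_integer_), class = "gt_field")
  mp <- file.path(dir, "molecules.csv")
  if (file.exists(mp)) {
    out$molecules <- readr::read_csv(mp, show_col_types = FALSE, progress = FALSE)
  }
  out
}
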