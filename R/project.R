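#' Assign molecules to cell outlines
#'
#' A molecule belongs to a cell if it lies inside the cell's outline
#' polygon or within `edge_tolerance_nm` of its boundary (default 30 nm,
#' about the localization precision of a membrane marker). Molecules
#' matching no cell are left unassigned (`cell_id = NA`); molecules
#' matching two or more cells go to the cell in which they are most
#' deeply contained (largest signed distance from the boundary), with
#' ties broken toward the lowest `cell_id` and logged. Overlapping
#' outlines are reported with a warning.
#'
#' @param mols Molecule tibble (`x_nm`, `y_nm`).
#' @param outlines Outline tibble (`cell_id`, `x_nm`, `y_nm`).
#' @param edge_tolerance_nm Boundary tolerance in nm (default 30).
#' @return `mols` with an added integer `cell_id` column (NA =
#'   unassigned).
#' @export
assign_molecules <- function(mols, outlines, edge_tolerance_nm = 30) {
  polys <- outline_split(outlines)
  ids <- as.integer(names(polys))
  np <- nrow(mols)
  best_depth <- rep(-Inf, np)
  best_cell <- rep(NA_integer_, np)
  tie <- logical(np)

  if (length(polys) > 1L) {
    for (i in seq_along(polys)[-length(polys)]) {
      for (j in seq((i + 1L), length(polys))) {
        pi_ <- polys[[i]]; pj <- polys[[j]]
        if (any(points_in_polygon(pi_[, 1], pi_[, 2], pj[, 1], pj[, 2])) ||
            any(points_in_polygon(pj[, 1], pj[, 2], pi_[, 1], pi_[, 2]))) {
          warn(paste0("assign_molecules: outlines ", ids[i], " and ", ids[j],
                      " overlap"))
        }
      }
    }
  }

  for (k in seq_along(polys)) {
    v <- polys[[k]]
    cand <- which(mols$x_nm >= min(v[, 1]) - edge_tolerance_nm &
                  mols$x_nm <= max(v[, 1]) + edge_tolerance_nm &
                  mols$y_nm >= min(v[, 2]) - edge_tolerance_nm &
                  mols$y_nm <= max(v[, 2]) + edge_tolerance_nm)
    if (!length(cand)) next
    depth <- points_containment_depth(mols$x_nm[cand], mols$y_nm[cand],
                                      v[, 1], v[, 2])
    hit <- depth >= -edge_tolerance_nm
    h <- cand[hit]; dh <- depth[hit]
    newtie <- dh == best_depth[h]
    better <- dh > best_depth[h]
    tie[h[newtie]] <- TRUE
    best_depth[h[better]] <- dh[better]
    best_cell[h[better]] <- ids[k]   # polys in ascending id order: ties keep lowest
    tie[h[better]] <- FALSE
  }
  if (any(tie & !is.na(best_cell))) {
    inform(paste0("assign_molecules: ", sum(tie & !is.na(best_cell)),
                  " molecules tied between cells; kept lowest cell_id"))
  }
  mols$cell_id <- best_cell
  mols
}

#' Project points into the normalized cell frame
#'
#' Maps raw coordinates into the cell frame defined by a fitted
#' [fit_arc()] model: a normalized longitudinal coordinate `s_raw`
#' running from -0.5 (pole a) to +0.5 (pole b), and a signed transverse
#' offset `d_nm` whose positive side is the outer (convex) curve —
#' radially farther from the arc center. Points whose angular position
#' falls beyond a pole (polar caps) keep their radial offset and have
#' `s_raw` clamped to the pole value with `clamped = TRUE`; they are
#' counted as polar by downstream zone statistics rather than dropped.
#'
#' For straight models `s_raw` is the (clamped) scalar projection onto
#' the pole axis and `d_nm` the signed perpendicular distance, positive
#' to the left of the a-to-b direction; the inner/outer distinction is
#' undefined without curvature (`curvature_defined = FALSE`).
#'
#' @param model An `arc_model`.
#' @param points Data frame or matrix of coordinates (`x_nm`, `y_nm` or
#'   two columns).
#' @return Tibble with `s_raw`, `d_nm`, `clamped`, `curvature_defined`.
#' @export
project_to_cell_frame <- function(model, points) {
  pts <- if (is.data.frame(points)) {
    cbind(points$x_nm, points$y_nm)
  } else {
    as.matrix(points)[, 1:2, drop = FALSE]
  }
  fc <- frame_coords(model, pts)
  s <- fc$s
  at_center <- fc$at_center
  if (any(at_center)) {
    warn("project_to_cell_frame: point(s) at the arc center; s undefined, clamped to 0")
    s[at_center] <- 0
  }
  clamped <- abs(s) > 0.5 | at_center
  s <- pmin(0.5, pmax(-0.5, s))
  tibble(s_raw = s, d_nm = fc$d, clamped = clamped,
         curvature_defined = model$kind == "arc")
}

# unclamped frame coordinates; s in cell-length units (pole a at -0.5)
frame_coords <- function(model, pts) {
  if (model$kind == "arc") {
    dx <- pts[, 1] - model$center_nm[1]
    dy <- pts[, 2] - model$center_nm[2]
    r <- sqrt(dx^2 + dy^2)
    phi_mid <- model$phi_a + model$sweep / 2
    s <- wrap_angle(atan2(dy, dx) - phi_mid) / model$sweep
    list(s = s, d = r - model$radius_nm, at_center = r < 1e-9)
  } else {
    u <- model$axis
    a <- model$pole_a_nm
    t <- ((pts[, 1] - a[1]) * u[1] + (pts[, 2] - a[2]) * u[2]) / model$length_nm
    d <- (pts[, 1] - a[1]) * (-u[2]) + (pts[, 2] - a[2]) * u[1]
    list(s = t - 0.5, d = d, at_center = rep(FALSE, nrow(pts)))
  }
}

#' Orient a cell by its principle pole
#'
#' Standardizes cell orientation so that the principle pole — the pole
#' holding more molecules of the protein of interest — sits at
#' `s_norm = -0.5`. Molecules are counted per cell half (`s < 0` vs
#' `s > 0`, `s = 0` excluded); if the positive half has strictly more,
#' all `s` values of the cell are negated. Transverse offsets are left
#' unchanged: reflecting along the arc does not change which radial side
#' a molecule is on. Ties keep the orientation as-is and are flagged.
#' The operation is idempotent.
#'
#' @param records Frame-coordinate tibble of one cell (columns `s_norm`
#'   or `s_raw`, `channel`).
#' @param channel Channel used for counting (the protein of interest,
#'   not the outline marker); `NULL` uses all records.
#' @return `records` with oriented `s_norm`, and attributes `flipped`,
#'   `orientation_tie`.
#' @export
orient_cell <- function(records, channel = NULL) {
  s_col <- if ("s_norm" %in% names(records)) "s_norm" else "s_raw"
  s_all <- records[[s_col]]
  sel <- if (!is.null(channel) && "channel" %in% names(records)) {
    records$channel == channel
  } else {
    rep(TRUE, nrow(records))
  }
  s <- s_all[sel]
  if (!length(s)) {
    warn("orient_cell: no molecules in the orientation channel; orientation kept")
    records$s_norm <- s_all
    attr(records, "flipped") <- FALSE
    attr(records, "orientation_tie") <- FALSE
    return(records)
  }
  n_neg <- sum(s < 0); n_pos <- sum(s > 0)
  flipped <- n_pos > n_neg
  tie <- n_pos == n_neg
  if (tie) inform("orient_cell: pole-count tie; orientation kept")
  records$s_norm <- if (flipped) -s_all else s_all
  attr(records, "flipped") <- flipped
  attr(records, "orientation_tie") <- tie
  records
}

#' Pool per-cell records into a population table
#'
#' Concatenates oriented per-cell frame records from one or more fields
#' into the population table that all quantification operates on. Rows
#' are keyed by `(field_id, cell_id)`; duplicate keys in the cell
#' metadata are an error. Per-cell fit metadata (length, rmse) is joined
#' in, axial/radial zone labels are attached, and the result is
#' deterministically ordered by field, cell and molecule index.
#'
#' @param records Tibble of frame records (`field_id`, `cell_id`,
#'   `channel`, `mol_id`, `x_nm`, `y_nm`, `s_norm`, `d_nm`, `clamped`,
#'   `curvature_defined`).
#' @param cells Tibble of cell metadata (`field_id`, `cell_id`,
#'   `length_nm`, `rmse_nm`).
#' @param polar_cutoff Axial zone boundary used for the zone labels
#'   (default 0.4; see [zone_fractions()]).
#' @return Population tibble (see [write_population_table()] for the
#'   column contract).
#' @export
pool_population <- function(records, cells, polar_cutoff = 0.4) {
  if (nrow(records) == 0L) {
    return(tibble(field_id = character(), cell_id = integer(),
                  channel = character(), mol_id = integer(),
                  x_nm = numeric(), y_nm = numeric(),
                  s_norm = numeric(), d_nm = numeric(),
                  clamped = logical(), curvature_defined = logical(),
                  zone_axial = character(), zone_radial = character(),
                  cell_length_nm = numeric(), fit_rmse_nm = numeric()))
  }
  if (anyDuplicated(cells[c("field_id", "cell_id")])) {
    abort("pool_population: duplicate (field_id, cell_id) keys in cell metadata")
  }
  meta <- cells %>%
    select(all_of(c("field_id", "cell_id", "length_nm", "rmse_nm"))) %>%
    rename(cell_length_nm = "length_nm", fit_rmse_nm = "rmse_nm")
  records %>%
    left_join(meta, by = c("field_id", "cell_id")) %>%
    mutate(
      zone_axial = case_when(
        .data$s_norm <= -polar_cutoff ~ "polar_principle",
        .data$s_norm >= polar_cutoff ~ "polar_secondary",
        TRUE ~ "middle"),
      zone_radial = case_when(
        !.data$curvature_defined ~ "undefined",
        .data$d_nm >= 0 ~ "outer",
        TRUE ~ "inner")) %>%
    arrange(.data$field_id, .data$cell_id, .data$mol_id)
}

#' Map molecules of a field into oriented cell frames
#'
#' High-level per-field driver: assigns molecules to outlines, builds a
#' mesh and arc fit per cell, projects each cell's molecules into the
#' normalized frame, orients every cell by its principle pole and pools
#' the result.
#'
#' @param mols Molecule tibble (`x_nm`, `y_nm`, `channel`).
#' @param outlines Outline tibble (`cell_id`, `x_nm`, `y_nm`).
#' @param field_id Field label (default "F1").
#' @param orient_channel Channel used for principle-pole orientation;
#'   `NULL` (default) counts all assigned molecules.
#' @param n_ribs,edge_tolerance_nm,straightness_ratio,polar_cutoff
#'   Parameters forwarded to [mesh_from_outline()], [assign_molecules()],
#'   [fit_arc()] and [pool_population()].
#' @return List with `population` (pooled tibble), `cells` (per-cell
#'   metadata: length, rmse, molecule count, flipped flag) and `models`
#'   (named list of `arc_model`s).
#' @export
map_cells <- function(mols, outlines, field_id = "F1",
                      orient_channel = NULL, n_ribs = 31L,
                      edge_tolerance_nm = 30, straightness_ratio = 15,
                      polar_cutoff = 0.4) {
  assigned <- assign_molecules(mols, outlines, edge_tolerance_nm)
  assigned$mol_id <- seq_len(nrow(assigned))
  ids <- sort(unique(outlines$cell_id))
  models <- list()
  cell_rows <- list()
  rec_rows <- list()
  for (id in ids) {
    ol <- outlines[outlines$cell_id == id, ]
    sub <- assigned[!is.na(assigned$cell_id) & assigned$cell_id == id, ]
    mesh <- tryCatch(mesh_from_outline(ol, n_ribs = n_ribs),
                     error = function(e) NULL)
    if (is.null(mesh)) {
      warn(paste0("map_cells: cell ", id, " has no usable mesh; skipped"))
      next
    }
    model <- fit_cell_arc(mesh, straightness_ratio)
    models[[as.character(id)]] <- model
    if (nrow(sub)) {
      proj <- project_to_cell_frame(model, sub)
      rec <- tibble(field_id = field_id, cell_id = id,
                    channel = sub$channel %||% "ch1",
                    mol_id = sub$mol_id,
                    x_nm = sub$x_nm, y_nm = sub$y_nm,
                    s_norm = proj$s_raw, d_nm = proj$d_nm,
                    clamped = proj$clamped,
                    curvature_defined = proj$curvature_defined)
      rec <- orient_cell(rec, channel = orient_channel)
      flipped <- attr(rec, "flipped")
    } else {
      rec <- NULL
      flipped <- FALSE
    }
    rec_rows[[as.character(id)]] <- rec
    cell_rows[[as.character(id)]] <- tibble(
      field_id = field_id, cell_id = id,
      length_nm = model$length_nm, rmse_nm = model$rmse_nm,
      kind = model$kind, n_molecules = nrow(sub), flipped = flipped)
  }
  cells <- bind_rows(cell_rows)
  records <- bind_rows(rec_rows)
  population <- pool_population(records, cells, polar_cutoff)
  list(population = population, cells = cells, models = models,
       n_unassigned = sum(is.na(assigned$cell_id)))
}
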