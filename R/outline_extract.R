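# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels that
# touch only diagonally are merged afterwards through a label graph.
label_components_8 <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nmax <- max(lab)
  if (nmax > 1L) {
    n <- nrow(lab); m <- ncol(lab)
    a1 <- lab[-n, -m]; b1 <- lab[-1, -1]    # \ diagonal
    a2 <- lab[-1, -m]; b2 <- lab[-n, -1]    # / diagonal
    sel1 <- a1 > 0 & b1 > 0 & a1 != b1
    sel2 <- a2 > 0 & b2 > 0 & a2 != b2
    edges <- rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2]))
    if (nrow(edges)) {
      g <- igraph::graph_from_data_frame(
        data.frame(from = as.character(edges[, 1]), to = as.character(edges[, 2])),
        directed = FALSE,
        vertices = data.frame(name = as.character(seq_len(nmax))))
      comp <- igraph::components(g)$membership
      remap <- integer(nmax)
      remap[as.integer(names(comp))] <- comp
      lab[lab > 0] <- remap[lab[lab > 0]]
    }
  }
  lab
}

#' Extract per-cell outlines from a binary mask
#'
#' Segments a binarized localization image into individual cell
#' outlines. Connected components are labeled with 8-connectivity and
#' their holes filled (a rendered membrane ring encloses an empty
#' interior). Components whose area falls outside `[min_area_nm2,
#' max_area_nm2]` or that come within `border_margin_nm` of the field
#' edge are discarded. Each kept component's outer contour is converted
#' to a polygon in nm, subsampled to at most `max_vertices` vertices and
#' smoothed by a 3-point moving average.
#'
#' `shrink_nm` optionally offsets each polygon inward. A membrane-marker
#' ring is broadened symmetrically by localization noise, so the
#' thresholded support extends outward by roughly the localization sigma
#' plus half a pixel; shrinking by that amount recovers the membrane
#' midline as the cell boundary.
#'
#' @param mask A `loc_mask` from [binarize()].
#' @param min_area_nm2,max_area_nm2 Component area limits in nm^2
#'   (defaults 0.2 and 6 um^2, bracketing 1-3 um vibrioid cells).
#' @param border_margin_nm Components with any pixel closer than this to
#'   the field edge are discarded (default 200).
#' @param shrink_nm Inward polygon offset in nm (default 0).
#' @param max_vertices Maximum vertices per outline (default 200).
#' @return Outline tibble: `cell_id`, `x_nm`, `y_nm` (vertices ordered
#'   along each boundary), ready for [mesh_from_outline()] and
#'   [assign_molecules()].
#' @export
extract_cell_outlines <- function(mask, min_area_nm2 = 0.2e6,
                                  max_area_nm2 = 6e6,
                                  border_margin_nm = 200,
                                  shrink_nm = 0, max_vertices = 200) {
  px <- mask$pixel_nm
  m <- mask$mask
  lab <- label_components_8(m)
  if (max(lab) == 0L) {
    return(tibble(cell_id = integer(), x_nm = numeric(), y_nm = numeric()))
  }
  lab <- matrix(as.integer(EBImage::fillHull(EBImage::Image(lab))),
                nrow(m), ncol(m))
  margin_px <- ceiling(border_margin_nm / px)
  nx <- nrow(lab); ny <- ncol(lab)

  keep_ids <- integer()
  for (id in sort(unique(lab[lab > 0]))) {
    sel <- lab == id
    area <- sum(sel) * px^2
    if (area < min_area_nm2 || area > max_area_nm2) next
    w <- which(sel, arr.ind = TRUE)
    if (min(w[, 1]) <= margin_px || max(w[, 1]) > nx - margin_px ||
        min(w[, 2]) <= margin_px || max(w[, 2]) > ny - margin_px) next
    keep_ids <- c(keep_ids, id)
  }
  if (!length(keep_ids)) {
    return(tibble(cell_id = integer(), x_nm = numeric(), y_nm = numeric()))
  }

  out <- vector("list", length(keep_ids))
  next_id <- 1L
  for (id in keep_ids) {
    # a merged 8-connected component may consist of several 4-connected
    # parts; trace each part and keep the largest contour as the outline
    comp <- EBImage::bwlabel(EBImage::Image((lab == id) * 1))
    ocs <- EBImage::ocontour(comp)
    oc_areas <- vapply(ocs, function(m) {
      if (nrow(m) < 4L) 0 else polygon_area(m[, 1], m[, 2])
    }, numeric(1))
    oc <- ocs[[which.max(oc_areas)]]
    # ocontour returns 0-based pixel indices; pixel centers in nm
    cx <- (oc[, 1] + 0.5) * px + mask$origin_nm[1]
    cy <- (oc[, 2] + 0.5) * px + mask$origin_nm[2]
    if (shrink_nm > 0) {
      sh <- polyclip::polyoffset(list(list(x = cx, y = cy)), -shrink_nm,
                                 jointype = "round")
      if (length(sh)) {
        areas <- vapply(sh, function(p) polygon_area(p$x, p$y), numeric(1))
        best <- sh[[which.max(areas)]]
        cx <- best$x; cy <- best$y
      }
    }
    if (length(cx) > max_vertices) {
      idx <- unique(round(seq(1, length(cx), length.out = max_vertices)))
      cx <- cx[idx]; cy <- cy[idx]
    }
    sm <- smooth_closed(cx, cy)
    if (nrow(sm) < 4L || polygon_area(sm[, 1], sm[, 2]) <= 0) next
    out[[next_id]] <- tibble(cell_id = next_id, x_nm = sm[, 1], y_nm = sm[, 2])
    next_id <- next_id + 1L
  }
  bind_rows(out)
}
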