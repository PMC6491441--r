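#' Per-cell map of molecules in the fitted cell
#'
#' Draws one cell: its outline, the fitted centerline arc and every
#' molecule as a cross, the single-cell view of the pipeline.
#'
#' @param outline Outline tibble of the cell (`x_nm`, `y_nm`).
#' @param model The cell's `arc_model`.
#' @param records Frame records of the cell (`x_nm`, `y_nm`).
#' @return A ggplot object.
#' @export
plot_cell_map <- function(outline, model, records = NULL) {
  ol <- tibble(x = c(outline$x_nm, outline$x_nm[1]),
               y = c(outline$y_nm, outline$y_nm[1]))
  if (model$kind == "arc") {
    phi <- seq(model$phi_a, model$phi_a + model$sweep, length.out = 100)
    cl <- tibble(x = model$center_nm[1] + model$radius_nm * cos(phi),
                 y = model$center_nm[2] + model$radius_nm * sin(phi))
  } else {
    cl <- tibble(x = c(model$pole_a_nm[1], model$pole_b_nm[1]),
                 y = c(model$pole_a_nm[2], model$pole_b_nm[2]))
  }
  p <- ggplot2::ggplot() +
    ggplot2::geom_path(data = ol, ggplot2::aes(.data$x, .data$y),
                       color = "grey40") +
    ggplot2::geom_path(data = cl, ggplot2::aes(.data$x, .data$y),
                       color = "steelblue", linewidth = 0.8) +
    ggplot2::coord_fixed() +
    ggplot2::scale_y_reverse() +   # image convention: y increases downward
    ggplot2::labs(x = "x (nm)", y = "y (nm)") +
    ggplot2::theme_minimal()
  if (!is.null(records) && nrow(records)) {
    p <- p + ggplot2::geom_point(
      data = records, ggplot2::aes(.data$x_nm, .data$y_nm),
      shape = 4, size = 1.2, color = "firebrick")
  }
  p
}

#' Population-level figures
#'
#' Builds the two standard population displays from a pooled table: the
#' axial histogram of `s_norm` and the oriented 2D map in `(s, d)` with
#' the four zone fractions annotated. Axis conventions are fixed:
#' `s` spans `[-0.5, 0.5]` (-0.5 = principle pole) and `d` spans
#' `[-d_max, d_max]` (+ = outer curve).
#'
#' @param table Population tibble.
#' @param n_bins Histogram bins (default 50).
#' @param polar_cutoff Zone boundary for the annotations (default 0.4).
#' @return List of ggplot objects: `histogram`, `map`.
#' @export
plot_population <- function(table, n_bins = 50L, polar_cutoff = 0.4) {
  if (!nrow(table)) {
    warn("plot_population: empty table, no figures")
    return(invisible(NULL))
  }
  hist_tbl <- axial_histogram(table, n_bins)
  p_hist <- ggplot2::ggplot(hist_tbl) +
    ggplot2::geom_col(ggplot2::aes(.data$s_mid, .data$density),
                      width = 1 / n_bins, fill = "steelblue") +
    ggplot2::scale_x_continuous(limits = c(-0.5, 0.5)) +
    ggplot2::labs(x = "normalized long-axis position s (-0.5 = principle pole)",
                  y = "fraction of molecules") +
    ggplot2::theme_minimal()

  zs <- zone_fractions(table, polar_cutoff)
  d_max <- max(abs(table$d_nm), 1)
  lab <- sprintf(
    "polar(principle) %.1f%%  polar(secondary) %.1f%%  middle %.1f%%\nouter %.1f%%  inner %.1f%%",
    100 * zs$frac_polar_principle, 100 * zs$frac_polar_secondary,
    100 * zs$frac_middle, 100 * zs$frac_outer, 100 * zs$frac_inner)
  p_map <- ggplot2::ggplot(table) +
    ggplot2::geom_point(ggplot2::aes(.data$s_norm, .data$d_nm),
                        shape = 4, size = 0.6, alpha = 0.4,
                        color = "firebrick") +
    ggplot2::geom_vline(xintercept = c(-polar_cutoff, polar_cutoff),
                        linetype = "dashed", color = "grey55") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", color = "grey55") +
    ggplot2::coord_cartesian(xlim = c(-0.5, 0.5), ylim = c(-d_max, d_max),
                             expand = FALSE) +
    ggplot2::labs(x = "normalized long-axis position s",
                  y = "transverse offset d (nm, + = outer curve)",
                  subtitle = lab) +
    ggplot2::theme_minimal()
  list(histogram = p_hist, map = p_map)
}

#' Autoplot methods
#'
#' `autoplot()` for the package's result objects: an `arc_model` draws
#' the fitted arc and poles; a `zone_summary` draws the zone-fraction
#' bars; a `gt_field` draws the ground-truth outlines.
#'
#' @param object Object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-arcell
NULL

#' @rdname autoplot-arcell
#' @export
autoplot.arc_model <- function(object, ...) {
  plot_cell_map(tibble(x_nm = numeric(), y_nm = numeric()), object)
}

#' @rdname autoplot-arcell
#' @export
autoplot.zone_summary <- function(object, ...) {
  tbl <- tibble(
    zone = factor(c("polar principle", "middle", "polar secondary",
                    "inner", "outer"),
                  levels = c("polar principle", "middle", "polar secondary",
                             "inner", "outer")),
    fraction = c(object$frac_polar_principle, object$frac_middle,
                 object$frac_polar_secondary, object$frac_inner,
                 object$frac_outer),
    family = c("axial", "axial", "axial", "radial", "radial"))
  ggplot2::ggplot(tbl) +
    ggplot2::geom_col(ggplot2::aes(.data$zone, .data$fraction,
                                   fill = .data$family)) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "fraction of molecules") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' @rdname autoplot-arcell
#' @export
autoplot.gt_field <- function(object, ...) {
  closed <- object$outlines %>%
    group_by(.data$cell_id) %>%
    group_split() %>%
    map(~ bind_rows(.x, .x[1, ])) %>%
    bind_rows()
  ggplot2::ggplot(closed) +
    ggplot2::geom_path(ggplot2::aes(.data$x_nm, .data$y_nm,
                                    group = .data$cell_id),
                       color = "grey30") +
    ggplot2::coord_fixed(xlim = c(0, object$field_nm),
                         ylim = c(object$field_nm, 0)) +
    ggplot2::labs(x = "x (nm)", y = "y (nm)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
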