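# canonical column set of the pooled population table
POPULATION_COLUMNS <- c("field_id", "cell_id", "channel", "mol_id",
                        "x_nm", "y_nm", "s_norm", "d_nm",
                        "clamped", "curvature_defined",
                        "zone_axial", "zone_radial",
                        "cell_length_nm", "fit_rmse_nm")

#' Write the pooled population table
#'
#' Serializes a population table (see [pool_population()]) as CSV with a
#' fixed, documented header: `field_id, cell_id, channel, mol_id, x_nm,
#' y_nm, s_norm, d_nm, clamped, curvature_defined, zone_axial,
#' zone_radial, cell_length_nm, fit_rmse_nm`. This delimited table is the
#' package's spreadsheet export: one row per molecule, directly loadable
#' into any spreadsheet or stats tool for pooling >100 cells across
#' fields. Numbers are written with 12 significant digits so a
#' write-then-read round trip reproduces values within 1e-6.
#'
#' @param table Population tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @seealso [read_population_table()]
#' @export
write_population_table <- function(table, path) {
  tbl <- as_tibble(table)
  for (col in POPULATION_COLUMNS) {
    if (!col %in% names(tbl)) {
      tbl[[col]] <- switch(col,
        field_id = , channel = , zone_axial = , zone_radial = character(nrow(tbl)),
        clamped = , curvature_defined = logical(nrow(tbl)),
        cell_id = , mol_id = integer(nrow(tbl)),
        numeric(nrow(tbl)))
    }
  }
  tbl <- tbl[POPULATION_COLUMNS]
  num <- vapply(tbl, is.numeric, logical(1)) & !vapply(tbl, is.integer, logical(1))
  tbl[num] <- lapply(tbl[num], function(v) formatC(v, digits = 12, format = "g"))
  readr::write_csv(tbl, path, progress = FALSE)
  invisible(path)
}

#' Read a pooled population table
#'
#' @param path CSV written by [write_population_table()].
#' @return Population tibble with typed columns.
#' @export
read_population_table <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("field_id", "cell_id", "channel", "s_norm", "d_nm"), names(tbl))
  if (length(missing)) {
    abort(paste0("population table ", path, " lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  tbl %>%
    mutate(field_id = as.character(.data$field_id),
           cell_id = as.integer(.data$cell_id),
           clamped = as.logical(.data$clamped),
           curvature_defined = as.logical(.data$curvature_defined))
}
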