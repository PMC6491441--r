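#' Read a single-molecule localization list
#'
#' Parses the delimited text molecule lists exported by localization
#' software into a tidy tibble of localizations in nanometres. Three
#' dialects are supported:
#'
#' * `"thunderstorm_csv"` — comma-separated with a header naming the
#'   coordinate columns in nm, e.g. `"x [nm]","y [nm]","frame"`.
#' * `"nstorm_txt"` — tab-separated vendor-style export with a header row;
#'   coordinate columns are matched case-insensitively by name, preferring
#'   drift-corrected `Xc`/`Yc` over `X`/`Y`, all interpreted as nm.
#' * `"arcell_csv"` — this package's own population/molecule CSV
#'   (columns `x_nm`, `y_nm`, ...).
#'
#' Rows with missing, non-finite or negative coordinates are dropped and
#' counted in the load report (see [molecule_load_report()]). Molecule
#' order is preserved and duplicate coordinates are kept: repeated
#' localizations of one blinking fluorophore are a property of the
#' upstream data, not something the reader should second-guess.
#'
#' @param path Path to the molecule-list text file.
#' @param dialect One of `"thunderstorm_csv"`, `"nstorm_txt"`,
#'   `"arcell_csv"`.
#' @param channel Channel label attached to every molecule (non-empty
#'   string), e.g. `"target"` or `"MTS"`.
#' @param extent_nm Numeric length-2 field extent (width, height) in nm.
#'   Defaults to the 40960 x 40960 nm field of a 256 x 256 pixel
#'   acquisition.
#'
#' @return A tibble with columns `x_nm`, `y_nm`, `frame`, `intensity`,
#'   `precision_nm`, `channel`, carrying attributes `extent_nm`,
#'   `dialect`, `source_path` and `load_report`.
#' @seealso [molecule_load_report()], [write_outline_set()]
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c('"x [nm]","y [nm]","frame"', "100.5,200.5,1", "300,400,2"), f)
#' read_molecule_list(f, "thunderstorm_csv", channel = "demo")
read_molecule_list <- function(path,
                               dialect = c("thunderstorm_csv", "nstorm_txt", "arcell_csv"),
                               channel = "ch1",
                               extent_nm = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("molecule list not found: ", path))
  if (!is.character(channel) || length(channel) != 1L || !nzchar(channel)) {
    abort("`channel` must be a non-empty string")
  }
  delim <- if (dialect == "nstorm_txt") "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE, trim_ws = TRUE,
                           name_repair = "minimal")
  if (nrow(raw) == 0L && ncol(raw) == 0L) {
    abort(paste0("empty molecule list with no header: ", path))
  }
  nm <- tolower(names(raw))

  pick <- function(candidates) {
    for (cand in candidates) {
      hit <- which(nm == cand)
      if (length(hit)) return(hit[1])
    }
    NA_integer_
  }
  cols <- switch(dialect,
    thunderstorm_csv = list(
      x = pick(c("x [nm]", "x[nm]", "x (nm)", "x")),
      y = pick(c("y [nm]", "y[nm]", "y (nm)", "y")),
      frame = pick("frame"),
      intensity = pick(c("intensity [photon]", "intensity [photons]", "intensity")),
      precision = pick(c("uncertainty [nm]", "uncertainty_xy [nm]", "uncertainty"))
    ),
    nstorm_txt = list(
      x = pick(c("xc", "x")),
      y = pick(c("yc", "y")),
      frame = pick("frame"),
      intensity = pick(c("height", "intensity", "photons")),
      precision = pick(c("lateral localization accuracy", "accuracy"))
    ),
    arcell_csv = list(
      x = pick("x_nm"), y = pick("y_nm"), frame = pick("frame"),
      intensity = pick("intensity"), precision = pick("precision_nm")
    )
  )
  if (is.na(cols$x) || is.na(cols$y)) {
    missing <- c(if (is.na(cols$x)) "x", if (is.na(cols$y)) "y")
    abort(paste0("molecule list ", path, " lacks mandatory column(s): ",
                 paste(missing, collapse = ", "),
                 " (dialect ", dialect, ")"))
  }

  num <- function(idx, default) {
    if (is.na(idx)) return(rep(default, nrow(raw)))
    suppressWarnings(as.numeric(raw[[idx]]))
  }
  x <- suppressWarnings(as.numeric(raw[[cols$x]]))
  y <- suppressWarnings(as.numeric(raw[[cols$y]]))
  keep <- is.finite(x) & is.finite(y) & x >= 0 & y >= 0
  n_in <- nrow(raw)

  mols <- tibble(
    x_nm = x[keep],
    y_nm = y[keep],
    frame = {
      f <- num(cols$frame, 0)[keep]
      as.integer(ifelse(is.finite(f) & f >= 0, f, 0))
    },
    intensity = {
      i <- num(cols$intensity, 0)[keep]
      ifelse(is.finite(i) & i >= 0, i, 0)
    },
    precision_nm = num(cols$precision, NA_real_)[keep],
    channel = channel
  )

  extent_nm <- extent_nm %||% ARCELL_DEFAULT_EXTENT
  stopifnot(length(extent_nm) == 2L, all(extent_nm > 0))
  report <- list(rows_in = n_in, molecules_kept = nrow(mols),
                 rows_dropped = n_in - nrow(mols))
  if (report$rows_dropped > 0) {
    inform(paste0("read_molecule_list: dropped ", report$rows_dropped,
                  " of ", n_in, " rows with invalid coordinates (", path, ")"))
  }
  attr(mols, "extent_nm") <- as.numeric(extent_nm)
  attr(mols, "dialect") <- dialect
  attr(mols, "source_path") <- path
  attr(mols, "load_report") <- report
  mols
}

#' Load report of a molecule list
#'
#' @param mols A tibble returned by [read_molecule_list()].
#' @return A list with `rows_in`, `molecules_kept`, `rows_dropped`.
#' @export
molecule_load_report <- function(mols) {
  attr(mols, "load_report") %||%
    list(rows_in = nrow(mols), molecules_kept = nrow(mols), rows_dropped = 0L)
}

# extent helper: attribute if present, else package default
ml_extent <- function(mols, extent_nm = NULL) {
  as.numeric(extent_nm %||% attr(mols, "extent_nm") %||% ARCELL_DEFAULT_EXTENT)
}

#' Write a molecule list as ThunderSTORM-style CSV
#'
#' Companion writer for [read_molecule_list()]; mainly used to persist
#' simulated channels so that they can re-enter the pipeline through the
#' same readers as real data.
#'
#' @param mols Molecule tibble (`x_nm`, `y_nm`, `frame`, ...).
#' @param path Output file path.
#' @param dialect Output dialect, `"thunderstorm_csv"` or `"nstorm_txt"`.
#' @return `path`, invisibly.
#' @export
write_molecule_list <- function(mols, path,
                                dialect = c("thunderstorm_csv", "nstorm_txt")) {
  dialect <- match.arg(dialect)
  frame <- if ("frame" %in% names(mols)) mols$frame else seq_len(nrow(mols))
  inten <- if ("intensity" %in% names(mols)) mols$intensity else 0
  if (dialect == "thunderstorm_csv") {
    out <- tibble(`x [nm]` = mols$x_nm, `y [nm]` = mols$y_nm,
                  frame = frame, intensity = inten)
    readr::write_csv(out, path, progress = FALSE)
  } else {
    out <- tibble(Xc = mols$x_nm, Yc = mols$y_nm, Frame = frame, Height = inten)
    readr::write_tsv(out, path, progress = FALSE)
  }
  invisible(path)
}
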