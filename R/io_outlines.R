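#' Read a set of cell outlines
#'
#' Parses the plain-text outline format used throughout this package:
#' one block per cell, a `cell <id>` line followed by one `x y` vertex
#' line per boundary point (nm, whitespace-separated, polygon stored open
#' with closure implied). Blank lines and `#` comments are ignored.
#'
#' Each polygon is validated: at least 4 vertices, simple
#' (non-self-intersecting) and of positive area. Invalid cells are
#' skipped with a warning rather than aborting the whole file.
#'
#' @param path Path to an outline text file.
#' @param field_id Field label attached to all outlines in the file.
#' @return A tibble of vertices with columns `field_id`, `cell_id`,
#'   `x_nm`, `y_nm`, ordered along each boundary.
#' @seealso [write_outline_set()]
#' @export
read_outline_set <- function(path, field_id = "F1") {
  if (!file.exists(path)) abort(paste0("outline file not found: ", path))
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  starts <- grep("^cell\\s+", lines)
  if (!length(starts)) {
    if (length(lines)) abort(paste0("no 'cell <id>' blocks in ", path))
    return(tibble(field_id = character(), cell_id = integer(),
                  x_nm = numeric(), y_nm = numeric()))
  }
  ends <- c(starts[-1] - 1L, length(lines))
  out <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    id <- as.integer(sub("^cell\\s+", "", lines[starts[k]]))
    body <- lines[seq(starts[k] + 1L, ends[k])]
    xy <- do.call(rbind, lapply(strsplit(body, "\\s+"), function(p) as.numeric(p[1:2])))
    ok <- TRUE
    if (nrow(xy) < 4L || anyNA(xy)) {
      ok <- FALSE
    } else if (polygon_area(xy[, 1], xy[, 2]) <= 0) {
      ok <- FALSE
    } else if (!polygon_is_simple(xy[, 1], xy[, 2])) {
      ok <- FALSE
    }
    if (!ok) {
      warn(paste0("skipping invalid outline for cell ", id, " in ", path))
      out[[k]] <- NULL
    } else {
      out[[k]] <- tibble(field_id = field_id, cell_id = id,
                         x_nm = xy[, 1], y_nm = xy[, 2])
    }
  }
  bind_rows(out)
}

#' Write a set of cell outlines
#'
#' Inverse of [read_outline_set()]; vertex coordinates are written with
#' enough digits to round-trip within 1e-6 nm.
#'
#' @param outlines Tibble with columns `cell_id`, `x_nm`, `y_nm` (and
#'   optionally `field_id`, ignored on write).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_outline_set <- function(outlines, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("# arcell outline set: per cell, 'cell <id>' then 'x y' in nm", con)
  for (chunk in split(outlines, outlines$cell_id)) {
    writeLines(paste("cell", chunk$cell_id[1]), con)
    writeLines(sprintf("%.9g %.9g", chunk$x_nm, chunk$y_nm), con)
  }
  invisible(path)
}

# split an outline tibble into a named list of per-cell vertex matrices
outline_split <- function(outlines) {
  keys <- unique(outlines$cell_id)
  setNames(lapply(keys, function(k) {
    v <- outlines[outlines$cell_id == k, ]
    cbind(x = v$x_nm, y = v$y_nm)
  }), keys)
}
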