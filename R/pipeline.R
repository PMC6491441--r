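#' Pipeline configuration
#'
#' Builds the flat key-value configuration that drives [run_pipeline()]
#' and the command-line interface. Every tunable of the pipeline is
#' named here with its default; unknown keys are rejected so that typos
#' in config files fail loudly. The effective configuration is echoed
#' into every output directory for reproducibility.
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of class `arcell_config`.
#' @export
arcell_config <- function(...) {
  defaults <- list(
    dialect = "thunderstorm_csv",   # molecule-list dialect
    extent_nm = 40960,              # square field side, nm
    pixel_nm = 32,                  # rendering pixel, nm
    render_mode = "counts",
    render_sigma_nm = 20,           # gaussian display rendering only
    binarize_method = "count",
    binarize_threshold = NA,        # for method = "fixed"
    closing_radius_nm = 64,
    min_count = 1,
    min_area_nm2 = 0.2e6,
    max_area_nm2 = 6e6,
    border_margin_nm = 200,
    shrink_nm = 30,                 # outline inward offset, ~sigma_loc + px/2
    max_vertices = 200,
    n_ribs = 31,
    edge_tolerance_nm = 30,
    straightness_ratio = 15,
    polar_cutoff = 0.4,
    density_factor = 2,
    min_molecules = 5,
    n_bins = 50,
    orient_channel = NA,            # NA = all molecules
    seed = 1,
    make_plots = TRUE
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    abort(paste0("arcell_config: unknown key(s): ",
                 paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(defaults, over)
  structure(cfg, class = "arcell_config")
}

#' Read / write a pipeline configuration
#'
#' YAML-subset persistence for [arcell_config()]; unknown keys in the
#' file are rejected.
#'
#' @param path Config file path.
#' @return For `read_config()`, an `arcell_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(arcell_config, vals)
}

#' @rdname read_config
#' @param config An `arcell_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' End-to-end driver: reads the target-channel molecule list, obtains
#' cell outlines either from an outline-marker molecule list (rendered,
#' binarized and segmented) or from a pre-drawn outline file — exactly
#' one of the two must be given — then assigns, fits, projects, orients
#' and pools all cells, and writes the population table, summaries,
#' plots, the effective config and a per-stage log into `out_dir`.
#' Outputs are deterministic given config and seeds.
#'
#' @param config An [arcell_config()].
#' @param molecules Target-channel molecule list: file path or tibble.
#' @param outline_molecules Outline-marker molecule list (path or
#'   tibble), or `NULL`.
#' @param outlines Pre-drawn outline file path or outline tibble, or
#'   `NULL`.
#' @param out_dir Output directory.
#' @param field_id Field label (default "F1").
#' @return Invisibly, a list with `population`, `cells`, `summary`,
#'   `out_dir`.
#' @export
run_pipeline <- function(config = arcell_config(), molecules,
                         outline_molecules = NULL, outlines = NULL,
                         out_dir, field_id = "F1") {
  if (is.null(outline_molecules) == is.null(outlines)) {
    abort("run_pipeline: give exactly one of `outline_molecules` or `outlines`")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  say <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    inform(line)
  }

  mols <- if (is.character(molecules)) {
    read_molecule_list(molecules, config$dialect, channel = "target",
                       extent_nm = rep(config$extent_nm, 2))
  } else molecules
  say("stage read: ", nrow(mols), " target molecules")

  if (!is.null(outline_molecules)) {
    omols <- if (is.character(outline_molecules)) {
      read_molecule_list(outline_molecules, config$dialect, channel = "marker",
                         extent_nm = rep(config$extent_nm, 2))
    } else outline_molecules
    say("stage read: ", nrow(omols), " outline-marker molecules")
    img <- render_localization_image(omols, pixel_nm = config$pixel_nm,
                                     mode = config$render_mode,
                                     sigma_nm = config$render_sigma_nm,
                                     extent_nm = rep(config$extent_nm, 2))
    say("stage render: ", nrow(img$counts), " x ", ncol(img$counts),
        " px, ", img$n_rendered, " molecules rendered")
    mask <- binarize(img, method = config$binarize_method,
                     threshold = if (is.na(config$binarize_threshold)) NULL
                                 else config$binarize_threshold,
                     closing_radius_nm = config$closing_radius_nm,
                     min_count = config$min_count)
    say("stage binarize: threshold ", signif(mask$threshold, 4),
        ", ", sum(mask$mask), " foreground px")
    ol <- extract_cell_outlines(mask, min_area_nm2 = config$min_area_nm2,
                                max_area_nm2 = config$max_area_nm2,
                                border_margin_nm = config$border_margin_nm,
                                shrink_nm = config$shrink_nm,
                                max_vertices = config$max_vertices)
    say("stage outline: ", length(unique(ol$cell_id)), " cells extracted")
  } else {
    ol <- if (is.character(outlines)) read_outline_set(outlines) else outlines
    say("stage outline: ", length(unique(ol$cell_id)), " cells loaded")
  }
  if (!nrow(ol)) abort("run_pipeline: no cell outlines")

  orient_channel <- if (is.na(config$orient_channel)) NULL else config$orient_channel
  mapped <- map_cells(mols, ol, field_id = field_id,
                      orient_channel = orient_channel,
                      n_ribs = config$n_ribs,
                      edge_tolerance_nm = config$edge_tolerance_nm,
                      straightness_ratio = config$straightness_ratio,
                      polar_cutoff = config$polar_cutoff)
  say("stage fit: ", nrow(mapped$cells), " cells fitted; ",
      nrow(mapped$population), " molecules mapped; ",
      mapped$n_unassigned, " unassigned")

  summary <- zone_fractions(mapped$population, config$polar_cutoff)
  write_population_table(mapped$population, file.path(out_dir, "population.csv"))
  write_outline_set(ol, file.path(out_dir, "outlines.txt"))
  readr::write_csv(mapped$cells, file.path(out_dir, "cells.csv"), progress = FALSE)
  jsonlite::write_json(as.list(summary), file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  write_config(config, file.path(out_dir, "config.yaml"))

  if (isTRUE(config$make_plots) && nrow(mapped$population)) {
    p1 <- plot_population(mapped$population, n_bins = config$n_bins,
                          polar_cutoff = config$polar_cutoff)
    ggplot2::ggsave(file.path(out_dir, "population_map.pdf"), p1$map,
                    width = 7, height = 5)
    ggplot2::ggsave(file.path(out_dir, "population_histogram.pdf"), p1$histogram,
                    width = 7, height = 5)
    say("stage plot: population figures written")
  }
  writeLines(c(paste0("arcell ", as.character(utils::packageVersion("arcell"))),
               log_lines),
             file.path(out_dir, "log.txt"))
  invisible(list(population = mapped$population, cells = mapped$cells,
                 summary = summary, out_dir = out_dir))
}
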