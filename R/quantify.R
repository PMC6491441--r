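#' Zone fractions of a molecule population
#'
#' Splits molecules into the axial zones polar-principle
#' (`s <= -polar_cutoff`), polar-secondary (`s >= +polar_cutoff`) and
#' middle cell body, and into outer/inner curve by the sign of the
#' transverse offset over curvature-defined molecules (`d = 0` counts as
#' outer and is logged). Cap molecules whose projection was clamped at a
#' pole enter the polar zones through their clamped `s`. The default
#' cutoff 0.4 calls the outermost 10% of the cell length at each pole
#' "polar".
#'
#' @param table Population tibble (needs `s_norm`, `d_nm`,
#'   `curvature_defined`).
#' @param polar_cutoff Axial zone boundary, 0 < cutoff < 0.5 (default
#'   0.4).
#' @return One-row tibble of class `zone_summary`: `n_total`,
#'   `frac_polar_principle`, `frac_polar_secondary`, `frac_middle`,
#'   `n_curved`, `frac_outer`, `frac_inner`, `polar_cutoff`.
#' @export
zone_fractions <- function(table, polar_cutoff = 0.4) {
  stopifnot(polar_cutoff > 0, polar_cutoff < 0.5)
  n <- nrow(table)
  if (n == 0L) {
    warn("zone_fractions: empty table; fractions are NaN")
    out <- tibble(n_total = 0L, frac_polar_principle = NaN,
                  frac_polar_secondary = NaN, frac_middle = NaN,
                  n_curved = 0L, frac_outer = NaN, frac_inner = NaN,
                  polar_cutoff = polar_cutoff)
    class(out) <- c("zone_summary", class(out))
    return(out)
  }
  s <- table$s_norm
  pp <- sum(s <= -polar_cutoff)
  ps <- sum(s >= polar_cutoff)
  curved <- table$curvature_defined
  d <- table$d_nm[curved]
  if (any(d == 0)) {
    inform(paste0("zone_fractions: ", sum(d == 0),
                  " molecules at d = 0 counted as outer"))
  }
  out <- tibble(
    n_total = n,
    frac_polar_principle = pp / n,
    frac_polar_secondary = ps / n,
    frac_middle = (n - pp - ps) / n,
    n_curved = length(d),
    frac_outer = if (length(d)) sum(d >= 0) / length(d) else NaN,
    frac_inner = if (length(d)) sum(d < 0) / length(d) else NaN,
    polar_cutoff = polar_cutoff)
  class(out) <- c("zone_summary", class(out))
  out
}

#' Axial histogram of normalized longitudinal positions
#'
#' Histogram of `s_norm` on equal-width bins spanning `[-0.5, 0.5]`;
#' `s = +0.5` falls in the last bin. This is the per-cell or pooled
#' "localization relative to the long axis" display.
#'
#' @param table Population tibble (needs `s_norm`).
#' @param n_bins Number of bins (>= 2, default 50).
#' @param normalize If `TRUE` (default) counts are normalized to sum
#'   to 1.
#' @return Tibble with `bin`, `s_lo`, `s_hi`, `s_mid`, `count`,
#'   `density` (normalized share).
#' @export
axial_histogram <- function(table, n_bins = 50L, normalize = TRUE) {
  stopifnot(n_bins >= 2L)
  edges <- seq(-0.5, 0.5, length.out = n_bins + 1L)
  bin <- pmin(findInterval(table$s_norm, edges, rightmost.closed = TRUE), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  tibble(bin = seq_len(n_bins),
         s_lo = edges[-(n_bins + 1L)],
         s_hi = edges[-1],
         s_mid = (edges[-1] + edges[-(n_bins + 1L)]) / 2,
         count = counts,
         density = if (sum(counts) > 0 && normalize) counts / sum(counts) else counts)
}

#' Radial offset between two boundary-tracing channels
#'
#' Estimates how much farther from the cell centerline channel B sits
#' than channel A — e.g. a periplasmic marker versus an inner-membrane
#' (MTS) marker, whose separation can be as small as a few tens of nm.
#' Both channels must be projected through the same cells; per cell the
#' offset is `median(|d|_B) - median(|d|_A)` restricted to the middle
#' zone (`|s| < polar_cutoff`, where the boundary runs parallel to the
#' centerline), and the across-cell median is returned with a seeded
#' bootstrap 95% interval. Cells with fewer than `min_molecules` in
#' either channel are excluded and counted.
#'
#' @param table_a,table_b Population tibbles of the two channels over
#'   the same cells.
#' @param polar_cutoff Middle-zone boundary (default 0.4).
#' @param min_molecules Minimum molecules per channel per cell (default
#'   20).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Bootstrap seed (default 1).
#' @return One-row tibble: `offset_nm`, `ci_lo_nm`, `ci_hi_nm`,
#'   `n_cells`, `n_cells_excluded`.
#' @export
radial_offset <- function(table_a, table_b, polar_cutoff = 0.4,
                          min_molecules = 20, n_boot = 1000, seed = 1) {
  mid <- function(tb) tb[abs(tb$s_norm) < polar_cutoff, ]
  a <- mid(table_a) %>%
    group_by(.data$field_id, .data$cell_id) %>%
    summarise(med_a = median(abs(.data$d_nm)), n_a = n(), .groups = "drop")
  b <- mid(table_b) %>%
    group_by(.data$field_id, .data$cell_id) %>%
    summarise(med_b = median(abs(.data$d_nm)), n_b = n(), .groups = "drop")
  per_cell <- dplyr::inner_join(a, b, by = c("field_id", "cell_id"))
  ok <- per_cell$n_a >= min_molecules & per_cell$n_b >= min_molecules
  excluded <- nrow(per_cell) - sum(ok)
  per_cell <- per_cell[ok, ]
  if (nrow(per_cell) == 0L) {
    warn("radial_offset: no cells with enough molecules in both channels")
    return(tibble(offset_nm = NaN, ci_lo_nm = NaN, ci_hi_nm = NaN,
                  n_cells = 0L, n_cells_excluded = excluded))
  }
  delta <- per_cell$med_b - per_cell$med_a
  est <- median(delta)
  boot <- withr_seed(seed, {
    vapply(seq_len(n_boot),
           function(i) median(delta[sample.int(length(delta), replace = TRUE)]),
           numeric(1))
  })
  ci <- quantile(boot, c(0.025, 0.975), names = FALSE)
  tibble(offset_nm = est, ci_lo_nm = ci[1], ci_hi_nm = ci[2],
         n_cells = nrow(per_cell), n_cells_excluded = excluded)
}

# evaluate expr under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}
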