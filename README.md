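# arcell

Arc-based cell coordinates for single-molecule localization microscopy
(PALM/STORM) of curved rod bacteria.

PALM experiments on bacteria produce *molecule lists* — one row per
detected fluorophore, at 10–30 nm precision — rather than images, and
standard image-analysis tools cannot relate those lists to subcellular
anatomy across hundreds of small, low-contrast cells. `arcell` solves
two problems for vibrioid (curved rod) bacteria such as *Vibrio
cholerae*:

1. **Outlining at localization precision.** Cell outlines are drawn
   from the localizations of a membrane (MTS-anchored) or periplasmic
   fluorescent-protein marker: the marker's molecule list is rendered
   into a localization image (default 32 nm pixels; a 40960 nm field
   becomes the 1280 × 1280 reconstruction grid), binarized, and
   segmented into per-cell outline polygons and meshes — no brightfield
   or phase-contrast images needed.
2. **A normalized, pole-oriented, curvature-aware cell frame.** Each
   cell's centerline is fitted with a circular arc whose arc angle
   gives the cell length, `L = R·|Δφ|`. Every molecule is mapped to

   * `s ∈ [−0.5, +0.5]` — normalized long-axis position, with `s = −0.5`
     at the **principle pole** (the pole holding more molecules of the
     protein of interest, used to orient all cells consistently), and
   * `d` (nm) — signed transverse offset from the centerline, positive
     on the **outer (convex) curve**, negative on the inner (concave)
     curve.

Molecules from >100 cells and many fields pool into one tidy table, on
which the package computes axial histograms, polar/middle and
inner/outer zone fractions, Voronoi-density cluster analysis
(simplified SR-Tesseler-style), and two-channel radial offsets able to
resolve the ~30 nm separation between inner-membrane and periplasmic
markers. A fully deterministic synthetic-field simulator provides
ground truth for every stage.

## Worked example

Simulate a paper-like field (15 curved cells in a 40960 nm field,
membrane marker at 15 nm precision, a polar protein with 80:20 pole
skew and a mild inner-curve bias), then run the full pipeline:

```r
library(arcell)
library(dplyr)

field  <- generate_field(n_cells = 15, seed = 7)
marker <- bind_rows(lapply(1:15, function(i)
  simulate_boundary_channel(field$cells[i, ], 3000, 0, 15,
                            seed = 700 + i, channel = "marker")))
target <- bind_rows(lapply(1:15, function(i)
  simulate_polar_channel(field$cells[i, ], 200, pole_ratio = 0.8,
                         side_bias = 0.6, seed = 750 + i,
                         channel = "target")))

res <- run_pipeline(arcell_config(), target,
                    outline_molecules = marker, out_dir = "out")
res$summary
#> # A tibble: 1 × 8
#>   n_total frac_polar_principle frac_polar_secondary frac_middle n_curved
#>     <int>                <dbl>                <dbl>       <dbl>    <int>
#> 1    3000                0.319               0.0903       0.591     3000
#> # i 3 more variables: frac_outer <dbl>, frac_inner <dbl>, polar_cutoff <dbl>
```

All 3000 target molecules were assigned to the 15 recovered cells. The
principle-pole fraction (0.319 at the `s ≤ −0.4` pole) versus the
secondary-pole fraction (0.090) reflects the generated 80:20 bipolar
skew plus the cytoplasmic pool, and `frac_inner = 0.607` recovers the
generated 0.6 inner-curve bias. Per-cell fits are tidy too:

```r
res$cells %>% select(cell_id, length_nm, rmse_nm, kind, n_molecules) %>% head(4)
#>   cell_id length_nm rmse_nm kind  n_molecules
#> 1       1     3124.    4.43 arc           200
#> 2       2     3082.    4.47 arc           200
#> 3       3     2265.    4.81 arc           200
#> 4       4     3544.    4.27 arc           200

ol  <- read_outline_set(file.path("out", "outlines.txt"))
fit <- fit_arc(with(mesh_from_outline(filter(ol, cell_id == 1)),
                    cbind(x_mid, y_mid)))
fit
#> <arc_model> circular arc: R = 1801.6 nm, sweep = 99.26 deg,
#>             length = 3121.23 nm, rmse = 3.63 nm
glance(fit)
#> # A tibble: 1 × 5
#>   kind  length_nm radius_nm rmse_nm     n
#> 1 arc       3121.     1802.    3.63    31
```

`out/` contains the population table (`population.csv`, one row per
molecule with `s_norm`, `d_nm` and zone labels), per-cell fits
(`cells.csv`), the zone summary (`summary.json`), the outlines, the
effective configuration, a per-stage log, and the population figures
(axial histogram and oriented 2D map). `plot_cell_map()`,
`plot_population()` and `autoplot()` methods draw the standard
single-cell and population views.

A thin command-line interface wraps the same functions
(`inst/scripts/arcell.R`; subcommands `simulate`, `outline`, `run`,
`quantify`, `cluster`).

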