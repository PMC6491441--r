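---
title: "Arc-based cell coordinates for PALM of curved rod bacteria: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Arc-based cell coordinates for PALM of curved rod bacteria: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arcell)
library(dplyr)
```

## The problem

Single-molecule localization microscopy (PALM/STORM) does not produce an
image but a *molecule list*: one row per detected fluorophore with
coordinates at 10--30 nm precision. Relating tens of thousands of such
localizations, spread over hundreds of bacterial cells and many fields
of view, to subcellular anatomy requires (i) cell outlines of comparable
precision, and (ii) a normalized cell coordinate system in which cells
of different lengths, curvatures and orientations can be pooled.

Both steps are hard for small, curved bacteria such as *Vibrio
cholerae*: brightfield contours are far coarser than the localization
data, and a simple long-axis projection ignores the distinction between
the inner (concave) and outer (convex) curve of a vibrioid cell —
a distinction that is biologically meaningful, because several polar
and cytoskeletal proteins distribute asymmetrically between the two
sides.

`arcell` addresses both steps:

1. **Outlining from localizations.** Membrane (MTS-anchored) or
   periplasmic fluorescent-protein markers trace the cell envelope at
   PALM precision. Their molecule list is rendered into a fine-pixel
   localization image, binarized, and segmented into per-cell outline
   polygons; a mesh (centerline + ribs) is built from each outline.
2. **The arc frame.** Each cell's centerline is fitted with a circular
   arc. The arc angle yields the cell length (`L = R |Δφ|`), the
   longitudinal position of every molecule is normalized to
   `s ∈ [−0.5, +0.5]` with `s = −0.5` at the *principle pole* (the pole
   holding more molecules of the protein of interest), and the
   transverse offset `d` (nm) is signed positive on the outer curve
   (radially farther from the arc center).

All coordinates are nanometres in image convention (origin top-left,
y down). The default field is 40960 × 40960 nm (a 256 × 256 pixel
EM-CCD acquisition) rendered at 32 nm pixels into a 1280 × 1280 grid.

## The shape model: a circular arc, not an ellipse

The centerline of a curved rod subtends a short arc. On short arcs a
general conic (ellipse) fit is ill-conditioned — small noise trades
eccentricity against orientation almost freely — while a circle is
well-determined, has a closed-form arc length, and induces an
unambiguous inner/outer side (the side toward/away from the arc
center). `fit_arc()` therefore uses the algebraic circle fit of Pratt
(generalized eigenvector of the moment matrix under the Pratt
constraint), which is nearly unbiased on short arcs, and falls back to
a total-least-squares line when the fitted radius exceeds
`straightness_ratio` (default 15) times the pole chord — straight
mutant cells are handled explicitly, and their molecules carry
`curvature_defined = FALSE` so that inner/outer statistics never
include cells without a defined curvature.

Molecules whose angular position falls beyond a pole (the polar caps)
keep their radial offset and have `s` clamped to ±0.5 with a `clamped`
flag; they are counted as polar by the zone statistics rather than
dropped, because polar clusters visibly cap the pole.

## Mesh construction

`mesh_from_outline()` proceeds in two passes.

*Pass 1 — provisional.* Pole seeds are the two farthest-separated
boundary regions (all point pairs within 1% of the maximal pairwise
separation, averaged per end) on a 256-point resampling of the contour.
The contour is split there into two banks, each bank resampled at equal
perimeter fractions, and rib midpoints give a provisional centerline.
A provisional arc is fitted to the cap-trimmed interior of that
centerline (points farther than 1.5 half-widths from either end).

*Pass 2 — refinement.* On a bent rod the farthest point pair sits on
the outer-curve corners of the caps, which bulges the provisional
centerline outward near the poles and flattens a naive arc fit (we
measured radius overestimates up to 2× without refinement). The final
poles are therefore the two crossings of the provisional midline
(circle or axis line) with the contour — the cap tip of a round-ended
cell, the middle of a flat end — and the final ribs are rebuilt
*perpendicular to the provisional midline* (radial rays from the arc
center), so that left/right bank points pair exactly opposite each
other. On noise-free synthetic cells this recovers radii to ~1 nm and
tip-to-tip lengths to 0.2%; perimeter-fraction pairing alone leaves a
systematic ~1–2 nm inward midline bias that measurably skews
inner/outer statistics.

Outlines with maximal separation below 1.3 equal-area-circle diameters
(`2.6·sqrt(area/π)`) raise a "no elongation axis" error: circles and
squares are rejected while the shortest, widest cells in the target
regime (≈1.6 µm tip-to-tip at 600 nm width, chord ≈1.5 µm) pass with
margin.

The per-cell arc used by the pipeline (`map_cells()`) is fitted on the
cap-trimmed interior centerline and then re-anchored at the full
centerline endpoints: cap midpoints pair across unequal bank lengths
and sit a nanometre or two inside the true midline, and excluding them
removes a small outward bias in `d`.

## Outlining from rendered localizations

`render_localization_image()` bins molecules into pixels (half-open
intervals, counts conserve molecules exactly); Gaussian rendering
exists for display only. `binarize()` defaults to a *count threshold*:
any pixel that received at least `min_count` (default 1) localizations
is foreground. A localization-count image is a Poisson sample of the
underlying structure, so for a specific membrane marker every rendered
localization is evidence of envelope; stray pixels are later removed by
the morphological closing (64 nm disk), hole filling and component-area
filters (0.2–6 µm², 200 nm border margin). Otsu thresholding on
log1p-transformed nonzero counts is available (`method = "otsu"`) for
data with substantial nonspecific background, but on clean membrane
rings it places the threshold *within* the signal and can open the ring
into an untraceable curve — which is why it is not the default.

The thresholded support of a membrane ring is broadened symmetrically
by localization noise, so the outer contour overshoots the membrane
midline by roughly the localization sigma plus half a pixel.
`extract_cell_outlines(shrink_nm = …)` offsets the polygon inward by
that amount (the pipeline default is 30 nm ≈ 15 nm marker precision +
16 nm half-pixel); with this correction tip-to-tip lengths of rendered
synthetic cells are recovered within ~2–3%.

## Orientation and pooling

`orient_cell()` counts molecules of the orientation channel per cell
half (`s < 0` vs `s > 0`); if the positive half holds strictly more,
all `s` of the cell are negated. Halves rather than polar zones are
used so that orientation does not depend on the zone cutoff. Ties keep
the current orientation and are flagged; the operation is idempotent.
Reflection along the arc does not change the radial side, so `d` is
untouched.

`pool_population()` concatenates per-cell records across fields keyed
by `(field_id, cell_id)`, joins per-cell fit metadata, attaches zone
labels, and orders rows deterministically, giving the population table
that every quantification — and the CSV export — consumes.

## Zones, clusters, radial offsets

**Zones.** The polar cutoff defaults to `|s| ≥ 0.4`, i.e. the outermost
10% of the cell length at each pole; it is a logged, mandatory
parameter because published zone boundaries for such analyses are
rarely stated. Inner/outer fractions are computed over all
curvature-defined molecules (a `middle-only` restriction is available
via the cutoff), with `d = 0` counted as outer and logged.

**Voronoi clusters.** `cluster_voronoi()` re-implements
Voronoi-density cluster detection (the SR-Tesseler approach) in
simplified form: tiles clipped to the cell polygon, local density
thresholded at `density_factor` (default 2) times the cell-wide average
density `n/area`, clusters as Voronoi-connected components of dense
molecules with at least `min_molecules` (default 5) members. Two
choices deserve explanation:

* *Density rank.* The bare inverse tile area has a heavy upper tail
  under complete spatial randomness: at factor 2, ~15% of uniformly
  placed molecules are "dense" and chance components of ≥5 appear in
  most fields. The default density is therefore the rank-2 Voronoi
  density (the molecule plus two rings of Voronoi neighbours, count
  over summed tile areas), under which uniform fields are practically
  never called clustered while genuine spots remain far above
  threshold. Rank 0 and 1 are available.
* *Growth.* The smoothed density deliberately under-covers a genuine
  cluster's rim, whose tiles open into the empty cell body. Detected
  clusters therefore absorb adjacent molecules whose bare tile density
  clears the threshold (hysteresis) and then one ring of immediate
  Voronoi neighbours. Growth never merges clusters and, absent a
  detected cluster, can create none — the null behaviour is untouched.

Because the original SR-Tesseler parameters used in published analyses
are unreported, this module makes no claim of numeric equivalence with
SR-Tesseler; it is a documented, tested stand-in with the same design.

**Radial offsets.** `radial_offset()` compares two boundary-tracing
channels through the *same* fitted cells: per cell the difference of
median `|d|` in the middle zone, then the across-cell median with a
seeded bootstrap interval. Using the same fitted arc for both channels
cancels centerline errors, which is what makes ~30 nm
membrane-vs-periplasm separations recoverable at 15 nm localization
noise.

## The synthetic-data generator

`generate_field()` and the two channel simulators define the study
conditions under which the package is validated: a 40960 nm square
field with ~15 cells; midline lengths 1–3 µm (mean cell size in the
emulated experiments is ~1.28 µm, and tip-to-tip length = midline +
width); width 600 nm; curvature radii 1.5–3 µm; cells placed with
≥400 nm clearance (sparse agarose-pad fields cover ~1% of the area, so
touching cells are rare) and a 500 nm field margin; boundary-marker
localization sigma 15 nm; membrane-to-periplasm radial offset 30 nm;
polar channels with pole ratio 0.8 (skewed bipolarity), polar sigma
150 nm (a few-hundred-nm polar cap), 15% cytoplasmic pool, and an
optional inner-curve bias applied per molecule by radial reflection
across the midline.

The generator emulates localization *lists*, not raw images: one
fluorophore yields one localization (no blinking/photophysics model),
there is no nonspecific background channel, and no drift. Passing
tests on these fields therefore demonstrate geometric correctness of
the pipeline, not robustness to blinking artefacts or background — on
real data the Otsu binarization option and the duplicate-position
jitter in the cluster module are the relevant knobs. Everything is
deterministic given `(parameters, seed)`.

## Numerical choices and degenerate inputs

* Polygons are stored open (closure implied); simplicity is checked by
  pairwise edge intersection; areas by the shoelace formula.
* Point-in-polygon uses the even-odd rule; assignment adds a boundary
  tolerance (default 30 nm ≈ membrane-marker precision) and resolves
  multi-matches by deepest containment, ties to the lowest cell id
  (logged).
* A molecule at the arc center has undefined `s`; it is clamped to the
  midpoint with a warning and `d = −R`.
* Exact duplicate positions entering the tessellation are jittered by
  0.1 nm on a deterministic golden-angle pattern (logged).
* Population CSVs carry 12 significant digits so that write-then-read
  round trips reproduce coordinates within 1e-6 nm.
* Bootstrap and all simulations take explicit seeds; the pipeline
  echoes its effective configuration into every output directory.

## Validation scale

The test-suite simulations are sized to finish in minutes on one core
while keeping the statistics meaningful: arc-length recovery over 100
noisy centerlines; a full rendered field of 15 cells at 3000 marker
molecules per cell; the inner-curve bias pooled over 105 cells × 100
molecules (the recovered fraction is compared against the 95% binomial
interval of the generating probability, so this check is itself a 95%
test by construction); the clustering null over 100 fields of 100
molecules. `scripts/acceptance.R` recomputes the same quantities from
scratch for any seed.

## Known limitations

* 2D only; no z information, no tracking, no per-frame kinetics.
* The arc model cannot represent S-shaped or branched cells; strongly
  aberrant outlines surface as high `rmse_nm` in the per-cell table.
* Outline extraction assumes cells do not touch; merged masks are
  rejected by the area filter rather than split.
* The cluster module's absolute numbers depend on the density rank and
  growth settings; comparisons across datasets should fix them.
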