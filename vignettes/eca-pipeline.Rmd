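---
title: "Delineating ecologically critical areas and explaining their change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating ecologically critical areas and explaining their change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecocrit)
```

## The problem

Ecologically critical areas (ECA) are the grid cells of a landscape that both
supply multiple ecosystem services at a high level and sit in a structurally
secure landscape context. Planners want to know where those cells are, how the
set of critical cells expands and degrades between survey dates, and which
environmental or socioeconomic drivers explain the change. `ecocrit`
implements that pipeline end to end on regular rasters (matrices; 1-km cells
by default), together with a fully seeded synthetic landscape generator so the
whole chain can be validated against planted ground truth.

## The model

**Criticality.** For each cell $i$ the Ecological Critical Index is the
product

$$\mathrm{ECI}_i = \mathrm{MESLI}_i \times \mathrm{LESSI}_i,$$

where $\mathrm{MESLI} = \sum_{s=1}^{n} \frac{x_s - \min x_s}{\max x_s - \min
x_s}$ sums the min–max normalised values of the $n$ service layers (carbon,
water yield, soil retention, habitat quality; range $[0, n]$), and LESSI is
the landscape ecological structure security index of the analysis unit
(county) the cell belongs to:

$$\mathrm{LESSI} = 1 - \big[(PD' + ED')\times 2.5\,V\big], \qquad
V = 0.5\,\mathrm{AWMSI}' + 0.3\,F' + 0.2\,D'.$$

$PD$ (patch density), $ED$ (edge density), AWMSI (area-weighted mean shape
index), $F$ (area-weighted fractal dimension) and $D$ (division) are
class-level patch metrics in the FRAGSTATS tradition, computed on patches
clipped to the unit. Primes denote min–max rescaling across units within a
period; the bracket is further divided by its cross-unit maximum (the default
`rescale = "cross_unit_max"`; a fixed theoretical denominator of 5 is also
available) so that LESSI lies in $[0,1]$. `2.5V` is read as the scalar product.
The weights 0.5/0.3/0.2 are the published convention and are arguments, not
constants.

Metric conventions worth stating exactly: a patch is a maximal connected
same-class cell set (8-connectivity by default, 4 available); patch perimeter
counts every exposed cell edge *including* unit and raster borders (so a
square patch filling its unit has AWMSI exactly 1), while $ED$ counts only
interior between-class edges, summed per class (a shared edge contributes to
both adjoining classes); a single-cell patch contributes the minimum fractal
dimension 1 (removable singularity of $2\ln(0.25p)/\ln a$ at $a = 1$). Both
per-unit (county) and moving-window LESSI are provided; per-unit is the
default because drivers are analysed at the county scale.

**Threshold.** The ECA threshold $T$ is extracted from the frequency
distribution of ECI: a histogram with `n_bins` (default 100) equal-width
bins, smoothed by a centred moving average (`smooth_window = 5`); peaks are
strict local maxima over interior bins, plateaus collapsing to their centre
bin; $T$ is the centre of the highest-ECI ("last") peak bin, and ECA is the
strict exceedance set $\{ \mathrm{ECI} > T \}$. One numerical guard is
essential at realistic sample sizes: a raw "last strict local maximum" rule
is hijacked by isolated straggler counts in the sparse right tail, which the
moving average turns into plateau-peaks. `extract_threshold()` therefore
requires a peak to reach `min_peak_frac` (default 0.08) of the smoothed
maximum. With the floor, the canonical recovery experiment (two-component
mixtures separated by at least 4 sd) lands within two bin widths of the upper
mode in effectively every replicate; without it, the rule fails even there.
If no qualifying interior peak exists the global maximum bin is used, with a
warning.

**Evolution.** Differencing two ECA masks yields expansion
($\neg t_1 \wedge t_2$), degradation ($t_1 \wedge \neg t_2$) and retained
cells. Changed cells whose 1-km buffers overlap form one patch (implemented
as connected components of the buffer-dilated mask, 4-connectivity,
restricted back to changed cells; on a 1-km grid the buffer of a cell is its
4-neighbour cross). Each patch gets a landscape expansion index

$$\mathrm{LEI} = 100\,\frac{A_0}{A_E - A_P} \in [0, 100],$$

with $A_P$ the patch area, $A_E$ the buffer-zone area (patch included, so the
denominator is the ring) and $A_0$ the reference-ECA area inside the buffer
zone. For expansion patches the reference is the earlier-date ECA; for
degradation patches it is the retained ECA by default (switchable to the
earlier mask), preserving the mirror reading — a lost patch surrounded by
surviving ECA is loss from within. Types follow the printed intervals:
expansion 0 → isolation, $(0, 50]$ → spread, $(50, 100]$ → infilling;
degradation mirrors these as departed, atrophy, disintegration.

**Drivers.** Rows are analysis unit × period pair. Twelve predictors: mean
DEM (m), mean slope (°), mean temperature (°C), total precipitation (mm),
forest/grassland/cropland area shares, mean GDP, population density, mean
nightlight, and mean Euclidean distances (km) from impervious and cropland
cells (computed by distance transform). Responses are the unit's dominant
evolution mode and dominant specific type per mode, ties breaking toward
degradation then lexicographically. A random forest (500 trees, $\sqrt{m}$
predictors per split, Gini impurity $1 - \sum_q p(q|t)^2$) is fitted per
response; accuracy is out-of-bag percent correct. Importance is the percent
Gini contribution

$$P(r) = \frac{\sum_{\text{trees}}\sum_{\text{nodes}} \Delta
\mathrm{Gini}_r}{\sum_{r'}\sum_{\text{trees}}\sum_{\text{nodes}} \Delta
\mathrm{Gini}_{r'}} \times 100,$$

which sums to 100 by construction. Grades I–VI come from geometric-interval
class breaks (widths in geometric progression over $[\min, \max]$, common
ratio selected over a grid including its inverse to balance class counts); a
published six-grade break preset (`grade_breaks_preset`) is bundled for
replication.

## What the synthetic generator emulates

`generate_timeseries()` builds a 96 × 96 landscape (1-km cells, 25
rectangular zones, four periods) with three service populations:

* a **degraded bulk** — class-conditioned service means (forest highest,
  impervious lowest) plus a smooth Gaussian noise field (sd 0.05,
  correlation length 3 cells);
* a **transitional semi-natural belt** (8% of cells, kept 2 km clear of the
  critical region) whose services sit at a common ceiling of 1.0 with gentle
  jitter; and
* **critical cores** (8% of cells) whose services exceed that ceiling by at
  least 0.4 — eight times the noise sd — plus a truncated-exponential excess
  (scale 0.3, capped at three scales).

This three-population design is deliberate and is the crux of making the
last-peak threshold testable. With only two populations the last histogram
peak *is* the critical mode, and a threshold at a mode's centre always cuts
off the mode's lower flank — no parameter choice recovers ≥ 90% of planted
cells. With the belt in place, the belt's mode forms the last interior peak,
the threshold settles just above it, every critical cell clears it, and the
false-positive rate is bounded by the belt's upper half (about 5% of cells).
The truncation of the exponential excess matters too: an uncapped tail both
stretches the min–max normalisation (collapsing the bulk into single-bin
spikes) and seeds straggler peaks.

Land cover is cluster-grown (multiplicatively weighted Voronoi around seeded
nuclei), coupled to the criticality field: intact forest-dominated interior,
a calmer agricultural mosaic outside, and one densely seeded "urban" corner
mosaic. The urban corner pins the maximum of every fragmentation axis, so
the cross-unit min–max rescale inside LESSI anchors its zero there rather
than at whichever ordinary unit happens to be most fragmented — without it,
an ECA-bearing unit occasionally lands at LESSI = 0 and its cells become
unrecoverable by construction. The urban corner is excluded from the truth
mask and from planted change.

Planted change between consecutive periods follows geometric placement
rules chosen so each planted set satisfies its intended LEI family exactly:
edge expansion picks cells 4-adjacent to the current ECA boundary; edge
degradation picks *promontory* cells with at least two open 4-neighbours
(removing a straight-boundary cell leaves three ECA neighbours in its ring —
LEI 75, which reads as disintegration, not edge retreat); edge picks are
spaced (squared distance ≥ 10) so buffers never merge into aggregates
sitting on the LEI = 50 boundary; isolated expansion picks cells more than
3 km from any ECA; isolated degradation removes whole isolated components;
interior expansion fills whole enclosed holes; interior degradation removes
spaced deep-core cells. Services move by the same per-cell uplift in both
directions, so degradation restores the pre-boost baseline exactly.

Each zone carries an evolution tendency (expansion- or degradation-prone),
stratified over the zones that can host boundary change and allocated
near-exclusively, and the configured driver (precipitation by default) is
shifted by ±3 raster sd according to that tendency — the known signal the
attribution stage must recover.

What the generator does **not** emulate: real service physics (no NPP or
hydrological modelling — service layers are consumed as given, which is also
the package's contract for real data), georeferencing and projections,
irregular county geometries, multi-date trajectories beyond pairwise
differencing, and observation error in land cover. Passing tests therefore
demonstrate that the pipeline's logic recovers known structure under
controlled conditions, not that any particular real landscape satisfies
those conditions.

## Numerical choices and degenerate inputs

* Histogram defaults 100 bins / smoothing 5 / peak floor 0.08; at least 1000
  finite ECI values are required.
* A constant service layer is an error (its min–max normalisation is
  undefined), named in the message.
* Units with no valid cells yield a `missing` metrics row and are excluded
  from rescaling.
* `LEI` is defined as 0 when the buffer ring is empty ($A_E = A_P$); empty
  patches and non-disjoint references are errors.
* Thresholds are re-extracted per period (per-period min–max normalisation,
  switchable in principle by pooling the inputs). A consequence visible in
  the worked example: when the threshold shifts between two dates, belt
  cells near the threshold flip status and appear as detected change. This
  is a property of the published extraction rule, not of the
  implementation; truth-based validation is therefore done against the
  planted masks.
* Determinism: every generator operation draws from a substream derived from
  the master seed, so adding operations never perturbs earlier draws;
  `fit_forest()` seeds the forest explicitly. Identical configs give
  byte-identical pipeline reports.

## Validation design

The test suite checks every stage against an independent path: patch
delineation and all five structure metrics against a plain flood-fill +
per-cell-loop oracle (50 random 32 × 32 landscapes, relative error below
$10^{-9}$); LEI geometry against cell enumeration by pairwise distances
(exact equality of $A_0$, $A_E$, $A_P$); threshold extraction against 100
seeded 4-sd mixtures (≥ 95 within two bin widths); the full pipeline against
20 seeded default scenarios (pooled planted-cell sensitivity ≥ 90%,
false-positive rate ≤ 10%, planted type-family accuracy ≥ 90%, planted
driver in the importance top 2 in ≥ 90% of runs); importance conservation to
$10^{-6}$; and chance-band out-of-bag accuracy (40–60%) on pure-noise
tables. Reporting arithmetic (mode proportions, percent change) is pinned to
published count pairs. The same quantities are recomputed from scratch by
`scripts/acceptance.R`.

## Known limitations

* LESSI's cross-unit rescaling makes the index relative to the period's own
  unit ensemble; comparisons across periods or study areas inherit that
  relativity (the `theoretical` rescale mode trades boundedness guarantees
  for comparability).
* The last-peak threshold is sensitive to histogram resolution in small
  samples; the peak floor stabilises it but the extracted $T$ remains a
  binned quantity with accuracy of order one bin width.
* The moving-window LESSI is quadratic in window size per cell and intended
  for small rasters or method comparison, not production-scale maps.
* Buffer geometry is raster-native (cell-centre distances); a vector-polygon
  buffer implementation would differ slightly at patch corners.
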