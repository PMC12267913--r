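---
title: "Methods: canopy gap dynamics from repeat canopy height models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: canopy gap dynamics from repeat canopy height models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models and procedures implemented in
`canopyflux`, the assumptions behind them, the parameters that matter, and
the design decisions taken where more than one reasonable choice existed.

## The change-classification model

The unit of observation is a pixel of two co-registered canopy height
models (CHMs, metres above ground, nominally 1-m pixels) acquired several
years apart. A **canopy gap** at one epoch is a connected component
(8-neighbor by default) of pixels with height strictly below a cutoff,
whose total area reaches a minimum size:

* `height_cutoff` — 10 m by default. The strict inequality `h < 10`
  mirrors the GF10 structure metric ("proportion of pixels < 10 m"), so the
  gap definition and the openness metric cannot disagree at the boundary.
  On continuous height data the choice of `<` versus `<=` is a
  measure-zero decision; it is pinned for reproducibility.
* `min_area` — 25 m² by default, about one canopy-tree crown: the
  definition captures treefalls and major crown damage while excluding
  inter-crown spacing and CHM noise. A relative mode (cutoff = 50% of the
  forest type's mean canopy height, minimum 10 m²) is available for
  comparisons across structurally distinct forests.
* `connectivity` — 8 by default (diagonal adjacency merges), matching the
  common raster-clump default; 4-neighbor is exposed for sensitivity
  checks because diagonal-only bridges can merge otherwise distinct
  openings.

Pixel-level change between the epochs is then classified by gap
membership first, disturbance second:

1. gap at both epochs → **gap persistence**;
2. gap at t1 only → **gap closure** ("recovered" simply means no longer a
   member of any qualifying t2 gap — covering both regrowth above the
   cutoff and shrinkage of a component below the minimum area; this keeps
   the five classes an exact partition);
3. gap at t2 only → **gap formation** (qualification is per gap object and
   per epoch, so the expansion fringe of an old gap counts as formation
   even when the newly opened sliver alone is under 25 m²);
4. otherwise, pixels in a connected region of height loss strictly greater
   than `disturbance_drop` (5 m) with area ≥ `disturbance_min_area`
   (25 m²) that contains no gap pixels → **canopy disturbance**;
5. everything else → **intact canopy**.

The five classes plus missing data tile the raster exactly; this partition
and the volume conservation it implies (the signed class volumes sum to
the total height change) are asserted by the test suite on every simulated
landscape.

### Cell rates and units

Rates are aggregated over 1-ha (100 × 100 m) cells — the scale at which a
single gap-forming event is still resolved but topography and forest type
are near-homogeneous within a cell. Volume change is height change times
pixel area, summed per class, divided by the acquisition interval in
decimal years (day count / 365.25), and normalised per hectare of valid
cell area (m³ ha⁻¹ yr⁻¹). *Losses* are the signed sum over formation and
disturbance, reported as absolute values; *gains* are the signed sum over
the other three classes and may legitimately be negative when intact
canopy or persistent gaps lose height; *net* = gains − losses.

A per-hectare *height* rate is ambiguous between two readings, and the
package emits both: `height_<class>` is the class-conditional mean height
change of that class's pixels (m yr⁻¹ — the reading under which closing
gaps rise by metres per year while intact canopy creeps by decimetres),
and `height_cell_<class>` divides by all valid pixels of the cell (the
reading under which the cell-level net height change is a small signed
number). The gains/losses/net height totals use the cell-normalised form;
analyses of volume are unaffected because volume has only one reading.

### Quality and retention rules

Pixels with pulse density below 2 m⁻² or scan angle above 20° are masked
(auxiliary rasters are optional; absent means the criterion passed — the
synthetic data has no acquisition artifacts). Cells are dropped when
incomplete (partial edge windows — equivalent to failing the missing-data
rule), when more than 5% of their area is missing, or when no forest type
reaches 75% of their area. Thresholds live in one `quality_thresholds()`
object so sensitivity analyses can vary them coherently.

## Terrain covariates

Elevation is averaged from the native DTM. Slope uses Horn's 3 × 3 kernel
on the DTM aggregated to 10 m (block mean; any missing input pixel voids
the block) — the de facto GIS standard; border pixels are undefined.

TWI is computed at 25-m resolution from the 10-m aggregate — coarse enough
to smooth over pit/mound microtopography and capture hillslope-scale
drainage. Because 25 is not an integer multiple of 10, the resample is an
exact area-weighted block mean (separable 1-D overlap weights), not an
integer-factor aggregation. The chain is:

1. **Pit filling** (Planchon–Darboux iterative fixpoint): every cell ends
   with a monotone descending path to the grid edge; a tiny enforced
   gradient (`eps = 1e-4` m per step) resolves flats deterministically.
   The operation is idempotent and never lowers any cell; cells adjacent
   to missing data act as edge outlets.
2. **D8 flow accumulation**: each cell drains to its steepest-descent
   neighbor of eight (drop divided by centre distance); ties are broken in
   the fixed order E, SE, S, SW, W, NW, N, NE for determinism.
   Accumulation counts the cell's own area and is reported as contributing
   area (m²). Single-direction routing was chosen over multiple-flow or
   D-infinity schemes as the simplest fully reproducible algorithm; only
   qualitative TWI behaviour (monotonicity in slope, valley > ridge,
   negative TWI–slope correlation) is relied on downstream, and exactly
   those properties are what the tests pin.
3. **TWI** = ln(a / tan β) with a = accumulation / cell width and β the
   Horn slope of the filled surface; tan β is floored at 0.001 so flats
   stay finite. TWI is invariant under elevation shifts by construction.

## Canopy structure metrics

Per cell: `h_mean` (mean of valid pixels), `h_max` (98th percentile,
linearly interpolated order statistics — pinned because percentile
conventions differ across software), `gf10` (fraction of pixels < 10 m)
and `h_cv`. For `h_cv` the requirements are an outlier-robust, 0–1-bounded
coefficient of height variation; the implementation uses the quantile
ratio (q95 − q5) / (q95 + q5), which satisfies both properties for
non-negative heights (insensitive to the extreme 5% tails, strictly < 1
for positive heights, 0 for all-zero input by convention). `h_mean` is
computed over all valid pixels, gap pixels included.

## The statistical layer

Responses are per-cell volume gain, loss and net rates. Losses are
right-skewed, so they are analysed as |y| and log-transformed before model
fitting; zero-loss cells (possible in the least dynamic zones) are handled
with log(y + c), c = 1 m³ ha⁻¹ yr⁻¹ — the smallest unit-scale constant —
recorded on the output, and back-transformed predictions are floored at
zero.

* **ANOVA among forest types** with Tukey HSD for the family-wise pairwise
  comparisons (the standard follow-up). Calibration is tested: the
  empirical type-I error over 10 000 seeded null replicates must lie in
  [0.04, 0.06] at α = 0.05.
* **Univariate regressions** `response ~ predictor × forest_type`
  (type-specific intercepts and slopes), alongside the pooled fit and
  pooled Pearson r; types with fewer than 3 cells are excluded from the
  interaction fit.
* **Multiple regressions** on standardized predictors (typically
  elevation, TWI, H_max, H_cv). These predictors are mutually correlated,
  so the package reports model-level R² only and deliberately offers no
  effect-size ranking between them.
* **Spatially buffered leave-one-out cross-validation**: gridded cells are
  spatially autocorrelated, so ordinary in-sample or LOO R² is optimistic.
  The buffer radius is the range of a spherical model fitted by unweighted
  least squares to the Matheron semivariogram of the model residuals
  (bin width = cell size, maximum lag = half the landscape diameter —
  the simplest reproducible estimator). Each cell is predicted from a
  model refitted on cells strictly beyond that range; spatial R² =
  1 − SSE/SST over the held-out predictions. A fitted partial sill below
  5% of the total sill is treated as "no usable structure" and the range
  reported as 0, which makes white-noise residuals reduce cleanly to
  ordinary LOO. Cells whose buffer leaves fewer than p + 2 training cells
  are skipped and counted. A single pre-computed residual range is used
  for all folds rather than per-fold re-estimation (the cheaper and more
  stable of the two defensible variants).

The buffer's behaviour is only meaningful when the landscape is several
times larger than the residual range; on domains comparable to the range
the training sets collapse and spatial R² degenerates — the acceptance
script therefore runs the regression layer on a 256-ha landscape
(16 × 16 cells).

## The synthetic landscape simulator

The simulator is the package's source of ground truth. It emulates the
structure the analysis assumes, with every quantity configurable:

* **Terrain**: base + relief × (sinusoidal ridge across x + gentle
  cross-slope in y), spanning c. 50–230 m by default, plus spectrally
  synthesised correlated noise (white noise filtered with an
  exp(−|f|·range) amplitude decay — fast, seeded and range-controllable).
* **Forest types** by elevation band: alluvial valleys below 110 m,
  sandstone mid-slopes to 180 m, kerangas above — emulating the
  valley-to-ridge fertility gradient, with canopy mean heights ordered
  alluvial (42 m) > sandstone (35 m) > kerangas (24 m).
* **Canopy fields** per type: correlated Gaussian fields (mean, sd,
  correlation range) floored at 12 m so background canopy can never read
  as gap, with disk-shaped initial gaps (floors uniform on [0, 8] m)
  injected at a per-type rate.
* **Dynamics** over one interval, in order: intact growth (+growth ×
  interval), per-gap Bernoulli closure (closed floors raised to ≥ 12 m),
  persistence (floor drift clipped below 8 m), Poisson disk-shaped gap
  formation, and Poisson disturbance patches whose drops are sampled so
  the post-drop canopy stays above 12.5 m. Finally Gaussian measurement
  noise (default sd 0.25 m) is added to the epoch-2 CHM.

Two deliberate idealisations: events are **disks** with overlap rejection
(1-pixel Chebyshev dilation keeps events 8-connectivity-separated), so
truth labels are unambiguous — real gaps are irregular, but shape enters
no implemented statistic beyond area and connectivity; and event
magnitudes keep a **2-m safety margin** from the 10-m and 5-m detection
thresholds. With the margin on and noise off, the classifier must
reproduce the truth labels at 100% of pixels, which separates correctness
testing from threshold-sensitivity testing (set `margin = 0` to study the
latter). With noise sd 0.25 m the margin corresponds to 8 standard
deviations, so agreement stays ≥ 99% by design. What passing these tests
does *not* show: robustness to co-registration error, CHM reconstruction
artifacts, irregular event geometry, or gradual multi-year dynamics —
none of which the simulator emulates.

Default rates were chosen once, against the closed-form expectation
calculator `expected_rates()`, so that the configured alluvial:kerangas
volume-loss ratio is ≈ 4.7 and the gain ratio ≈ 2.5 with per-type loss
magnitudes of order 10³ m³ ha⁻¹ yr⁻¹ — the contrast structure the analysis
is designed to resolve. Disturbance-drop distributions are per-type
(taller canopy admits deeper drops) because a drop must fit between the
pre-event canopy and the 12-m floor; placement rejection slightly favours
locally taller canopy, a small bias covered by the 10% tolerance at which
simulation-estimated ratios are compared with the configured expectations.

## Numerical and interface choices

* Rasters are carried in a minimal container (matrix + lower-left origin,
  square pixel size, nodata sentinel, CRS text) and serialised as ESRI
  ASCII grids with `%.17g` formatting, so a write/read round trip is
  bit-exact; `NA` never silently becomes a finite height (writing a grid
  whose finite values collide with the sentinel is an error).
* Pixel (1,1) is the top-left (north-west) corner; cell windows are
  half-open so tiling is an exact partition; partial edge cells are
  flagged and excluded.
* Connected components are labelled through the pixel-adjacency graph
  (igraph), with components numbered in raster-scan order of their first
  pixel; the test suite checks the labelling against an independent
  min-label-propagation fixpoint oracle on 1 000 random masks under both
  connectivities.
* Area thresholds are compared with a 10⁻⁹ slack so a 25-pixel component
  at 1-m resolution meets a 25-m² threshold regardless of floating-point
  representation.
* Degenerate inputs are defined, not accidental: empty gap sets give
  empty tables and fraction 0; empty classes give rate 0 and fraction 0;
  constant residuals give range 0; all-zero heights give `h_cv` 0.

## Problem sizes

The default simulated landscape is 25 ha (500 × 500 m at 1 m), on which
the full simulate–classify–summarise chain runs in seconds; the test suite
uses 4-ha landscapes for replicated property checks (100 seeds), 20
replicate 25-ha landscapes for rate recovery, a 30 × 30-cell grid for the
cross-validation calibration, and the acceptance script a 256-ha landscape
for the regression layer. These sizes were chosen so every stochastic
check rests on enough replication to be stable while the whole suite
remains quick to run routinely.

## Known limitations

* No reprojection or cross-CRS resampling: inputs must already be
  co-registered on a common grid (alignment is verified, not repaired).
* Quality masking applies to the CHM raster, not to the point cloud from
  which a CHM is built; point-cloud processing and CHM/DTM generation are
  out of scope.
* D8/TWI is one defensible hydrological model among several; only its
  qualitative behaviour should be interpreted.
* The decomposition of gap closure into vertical regrowth versus lateral
  crown expansion is not implemented, and the package measures canopy
  volume, not biomass.
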