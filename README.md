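# canopyflux

Quantifying forest canopy dynamics from repeat airborne laser scanning
(ALS) surveys. Given two co-registered canopy height models (CHMs) and a
digital terrain model (DTM), `canopyflux`:

1. **segments canopy gaps** — connected regions of the CHM below a height
   cutoff (default **h < 10 m**) covering at least a minimum area (default
   **≥ 25 m²**, roughly one canopy-tree crown), under 4- or 8-neighbor
   connectivity, with an optional forest-type-relative cutoff (50% of mean
   canopy height);
2. **classifies per-pixel change** between the two epochs into five dynamic
   classes: *gap formation* (new qualifying gaps), *canopy disturbance*
   (contiguous height loss > 5 m over ≥ 25 m² that does not open a gap),
   *gap persistence*, *gap closure*, and *intact canopy*;
3. **aggregates 1-ha cell rates** — per-class area fractions, height-change
   rates (m yr⁻¹) and volume-change rates (m³ ha⁻¹ yr⁻¹, volume = height ×
   area), grouped into canopy **losses** (formation + disturbance, reported
   as absolute values) and **gains** (the other three classes, signed — gains
   can be negative), with net change = gains − losses;
4. **derives covariates** per cell: mean elevation, Horn slope of the 10-m
   DTM aggregate, topographic wetness index TWI = ln(a / tan β) from D8 flow
   accumulation at 25-m resolution, and canopy structure metrics H_mean,
   H_max (98th CHM percentile), H_cv (outlier-robust quantile-ratio CV,
   bounded 0–1) and GF10 (fraction of pixels < 10 m);
5. **fits the statistical layer** — one-way ANOVAs among forest types with
   Tukey HSD, univariate regressions with a forest-type interaction,
   multiple regressions on standardized predictors, and spatially buffered
   leave-one-out cross-validation, where each held-out cell is predicted
   from cells beyond the residual autocorrelation range (fitted with a
   spherical semivariogram model), giving an optimism-corrected R².

Pixels with pulse density < 2 m⁻² or scan angle > 20° are masked; 1-ha cells
with > 5% missing data, incomplete extent, or no forest type covering ≥ 75%
of their area are excluded.

A **synthetic landscape simulator** generates DTM/CHM pairs with a terrain
gradient defining three forest-type zones (alluvial, sandstone, kerangas),
spatially correlated type-specific canopy fields, and disk-shaped dynamic
events with per-pixel truth labels, so the whole pipeline is validated
end-to-end with known truth and no external data.

The package is aimed at forest and remote-sensing ecologists analysing
repeat ALS acquisitions over structurally heterogeneous landscapes.

## Worked example

Simulate a 25-ha landscape, classify change, and summarise per-type rates:

```r
library(canopyflux)

cfg     <- landscape_config(seed = 42)      # 500 x 500 m at 1-m pixels
sim     <- simulate_landscape(cfg)
change  <- classify_change(sim$pair)
records <- cell_records(sim$pair, sim$dtm, sim$types)

aggregate(cbind(gains_volume, losses_volume, net_volume) ~ forest_type,
          records, mean)
#>   forest_type gains_volume losses_volume net_volume
#> 1    alluvial         3058          4285      -1227
#> 2    kerangas         1265          1099        166
#> 3   sandstone         2129          1827        301

anova_by_type(records, "losses_volume")$anova
#>      F df_between df_within        p
#> 1 20.8          2        17 2.72e-05

mean(change$class_map$values == sim$truth$values)
#> [1] 1
```

The volume rates are m³ of canopy per hectare per year: valley-bottom
alluvial forest both loses (4285) and gains (3058) canopy volume much
faster than the nutrient-poor kerangas zone (1099 / 1265), and the ANOVA
confirms the between-type contrast. The last line checks the classifier
against the simulator's per-pixel truth labels — agreement is exact here
because simulated event magnitudes keep a 2-m safety margin from the
detection thresholds.

A thin command-line wrapper is installed at `exec/canopyflux`
(subcommands `run`, `simulate`, `gaps`, `terrain`, `structure`, `change`,
`stats`); rasters are read and written as ESRI ASCII grids.

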