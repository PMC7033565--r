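# gaiseason

Whole-season prediction and evaluation of the **green area index** (GAI,
green plant area per unit ground area, m² m⁻²) of winter wheat from
four-band multispectral reflectance (green 550 nm, red 660 nm, red edge
735 nm, NIR 790 nm), as acquired by UAV-mounted sensors.

It is written for crop scientists and phenotyping groups who have
plot-level reflectance (tables, or per-band rasters plus plot polygons)
and want calibrated GAI estimates from tillering through senescence,
plus the downstream agronomy: per-class error diagnostics, a
chlorophyll-based evaluation during senescence, and green-area-duration
integration against final biomass.

## The models

All shipped models are built from band ratios, which cancel the
per-date multiplicative irradiance factor that destabilizes raw-band
calibrations. The registry (`gai_registry()`) holds six calibrated
equations, among them:

* the simple-ratio linear models, e.g.
  `GAI = −5.498 + 4.64 · NIR/RE`;
* **VIQUO**, a linear combination of all three NIR-based ratios the
  sensor supports,
  `GAI = −2.829243 + 1.814068 · NIR/RE − 0.004532 · NIR/Red + 0.321576 · NIR/Green`,
  the recommended model: sensitive up to GAI ≈ 5 m² m⁻², stable across
  the season, and simple enough to communicate;
* an exponential NDVI model `GAI = 0.00197 · exp(8.42847 · NDVI)`,
  accurate at sparse cover but saturating above GAI ≈ 2.

Refitting machinery (`fit_vi_model()`) and a date-grouped
cross-validation harness for machine-learning comparators
(`fit_advanced_model()`: PLS, SVM, KNN, MARS, boosted trees) sit behind
the same prediction contract. Hold-out samples are always whole flight
dates, and centring/scaling statistics never leak from hold-out rows —
both properties are asserted in the test suite.

A synthetic-data module (`forward_model_config()`,
`generate_calibration_set()`, `generate_spad_trial()`,
`generate_season()`) emulates the study structure — Beer–Lambert band
saturation, per-date irradiance, seasonal GAI trajectories, layered
chlorophyll decline, biomass proportional to green area duration — so
the whole pipeline is testable without field data.

## Worked example

```r
library(gaiseason)
reg <- gai_registry()

# one plot-level reflectance record (fractions) at full canopy
rec <- data.frame(green = 0.065, red = 0.042, red_edge = 0.31, nir = 0.52)
p <- compute_predictors(rec)
p[, c("nir_green", "nir_red", "nir_re", "ndvi")]
#>   nir_green nir_red nir_re  ndvi
#> 1         8  12.381  1.677 0.851

predict_gai(reg$VIQUO, p)     # 2.73 m2 m-2
predict_gai(reg$NIR_RE, p)    # 2.29 m2 m-2
predict_gai(reg$NDVI_exp, p)  # 2.56 m2 m-2
```

The NDVI here (0.85) is deep in the saturation zone, so the exponential
NDVI model is at the edge of its useful range, while the red-edge-based
ratios still discriminate — the motivation for VIQUO.

A whole season, end to end on synthetic data:

```r
seas <- generate_season(forward_model_config(n_plots = 12),
                        biomass_noise_sd = 0.05)
cal <- generate_calibration_set()
cal2 <- compute_predictors(cal); cal2$gai <- cal$gai_true
viquo <- fit_vi_model(cal2[cal2$valid, ], "ratio_linear",
                      c("nir_re", "nir_red", "nir_green"))
ser <- predict_season(seas$reflectance, viquo)
pr <- progressive_r2(ser, seas$biomass)
pr$r2[nrow(pr)]
#> [1] 0.928
```

Predicted GAI per flight is interpolated daily, integrated to green
area duration (GAD, m² m⁻² d), and correlated with final biomass: 93 %
of the biomass variance is explained at the final date on this run.

## The analysis workflow

The `analysis/` directory is a numbered, re-runnable narrative over the
package functions:

| script | what it does | output (results/) |
|---|---|---|
| `01_simulate.R` | generates calibration, season and SPAD trials | `effective_config.json` |
| `02_vi_models.R` | calibrates the six VI models, held-out-date evaluation | `vi_model_comparison.csv` |
| `03_advanced_models.R` | grid-searched learners under date-grouped CV | `advanced_model_comparison.csv` |
| `04_class_evaluation.R` | seven-class error breakdown, cultivar ANOVA | `class_breakdown.csv`, `cultivar_comparison.csv` |
| `05_senescence.R` | SPAD → canopy greenness, agreement with predictions | `greenness_weibull_parameters.csv`, `senescence_agreement.csv` |
| `06_season_gad.R` | daily interpolation, GAD, progressive R² vs biomass | `green_area_duration.csv`, `progressive_r2.csv` |

Run them in order with `Rscript analysis/01_simulate.R` etc.; raw
simulated tables land in `scratch/` and summary tables in `results/`.

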