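---
title: "Whole-season GAI prediction: models, evaluation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-season GAI prediction: models, evaluation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaiseason)
```

## The problem

The green area index (GAI, green plant area per unit ground area,
m^2^ m^-2^) summarizes how much photosynthetically active surface a crop
canopy exposes. It drives light interception and transpiration, so
agronomists want it repeatedly through the season, on many plots, without
destructive sampling. Four-band multispectral cameras on small UAVs
deliver plot-level reflectance in green (550 nm), red (660 nm), red edge
(735 nm) and NIR (790 nm); the statistical question is how to turn those
four numbers into a GAI estimate that works from tillering through
senescence.

Two obstacles shape everything in this package:

* **Saturation.** Red reflectance is nearly exhausted once the canopy
  closes; NDVI consequently stops responding above a GAI of roughly
  2–3 m^2^ m^-2^. The red-edge band keeps discriminating in dense
  canopies, which is why ratios involving it carry most of the late-season
  signal.
* **Irradiance instability.** Raw band values shift with per-date
  illumination. A multiplicative factor common to all bands of a date
  cancels exactly in band ratios — the reason all shipped models are
  ratio-based.

## The calibrated models

The registry (`gai_registry()`) holds six calibrated equations: the three
NIR simple ratios, the four-band combination of all three ratios (VIQUO,
the recommended model), its full 8-term interaction expansion, and an
exponential NDVI model

$$\widehat{GAI} = a\,e^{b\cdot NDVI},$$

which concentrates its sensitivity at sparse cover. Coefficients are
stored verbatim in a JSON data file and are read-only; refitting always
produces a new model object whose provenance says so. Predictions are
never clipped at zero inside `predict_gai()`: the NIR/RE model's negative
low-GAI predictions are a documented behaviour that the season
diagnostics rely on, so clipping is an explicit opt-in flag.

`fit_vi_model()` refits any of these forms by OLS (the exponential by
bounded Levenberg–Marquardt, initialized from a log-linear fit of
log(GAI + 0.001), a start that is robust because the response is strictly
positive after the shift and the exponential is monotone).

## Machine-learning comparators and CV hygiene

Six learner families sit behind one contract (`fit_advanced_model()`):
partial least squares, linear- and radial-kernel SVM regression, k-nearest
neighbours, multivariate adaptive regression splines, and boosted trees
(minimum node size fixed at 10). Tuning is a grid search selected by
cross-validated RMSE. Two hygiene rules are enforced and tested rather
than assumed:

* **Folds are dates.** A flight date is a block: atmospheric conditions,
  sun angle and phenology are shared within it, so records of one date
  never appear on both sides of a split (`date_grouped_folds()`).
* **Scaling statistics are training statistics.** For the learners that
  need centred/scaled inputs, the means and SDs come from the training
  split of each fold only. The test suite includes a crafted dataset on
  which a deliberately leaky implementation gives a measurably different
  CV error, and asserts the harness matches the leak-free oracle.

Grid-search ties go to the first grid point in declared order, making the
selection deterministic. Default grids are small and conventional (SVM
cost over powers of two, 1–4 PLS components, KNN k in 3–9, MARS degree
1–2, boosted trees depth 1–3 by 50–500 trees); they are arguments, not
constants. MARS is implemented in the package (forward hinge-pair
selection with GCV backward pruning) since no MARS implementation is
available in the supported dependency set; with a handful of predictors
this compact implementation is adequate.

## Error metrics and the seven GAI classes

MAE is the primary comparison metric — prediction quality at low GAI
matters as much as at high GAI because light interception is nonlinear in
GAI — with RMSE reported for comparability. `class_breakdown()` resolves
error over seven classes of *observed* GAI: an exact-zero "DeadPlant"
class, (0, 0.25), [0.25, 2), [2, 3), [3, 4), [4, 5) and [5, ∞). Boundaries
belong to the upper (left-closed) class for determinism. The relative MAE
divides by the class mean of observed GAI and is therefore NA — not 0, not
Inf — for the dead-plant class. Two identities are enforced to 1e-12 in
tests: n-weighted class MAEs recombine to the global MAE, and rMAE is
invariant to rescaling both series.

Reference GAI values above 7 m^2^ m^-2^ are excluded before calibration
(`apply_cleaning_filters()`, strictly-above rule so the boundary value
survives); exclusions are logged, never silent.

For the cultivar question, `cultivar_model_comparison()` fits nested
linear models with and without cultivar × predictor interaction and
reports the F-test p-value plus MAEs and RMSEs on both splits. One
caution discovered while testing: nested least squares guarantees the
*RMSE* ordering on the fit split (extended ≤ common), but the analogous
MAE ordering is **not** a theorem and occasionally inverts on noisy data;
both metrics are therefore reported and only the RMSE ordering is
asserted.

## Senescence: evaluating GAI models when ground truth dissolves

After flowering, "green area" stops being destructively measurable: organ
death is zonal while chlorophyll degrades gradually. The package's answer
is a chlorophyll-based reference. SPAD readings per leaf layer are
converted with the exponential calibration chl = a·e^(b·SPAD) (coefficients
are user-supplied — they are species-specific and published externally,
so hard-coding them would be false precision), weighted by each layer's
share of canopy leaf area, and summed to a canopy chlorophyll
concentration. Per plot, a declining Weibull-type curve

$$chl(t) = lo + (hi - lo)\,e^{-(t/\lambda)^k}$$

is fitted over thermal time (five seeded multi-starts, bounds
lo ≥ 0; thermal time is cumulative daily mean temperature above a 0 °C
base, configurable). **Measured canopy greenness** reduces every value by
the minimum value of the fit and divides by the maximum of the
min-reduced fit. We take the curve's extremes as a function — lower
asymptote `lo`, maximum `hi` at thermal time zero — so greenness is
exactly 1 at the fitted maximum and decays to exactly 0 at the fitted
minimum regardless of how far the observation grid extends; normalizing
by the fitted values at the observed times instead would break the
asymptote identity whenever measurements stop near the decline. The two
readings coincide as the observation window widens.

**Predicted canopy greenness** divides post-onset GAI predictions by the
prediction at the onset date, so both series are 1 at onset by
construction; `greenness_agreement()` consequently *excludes* the onset
date from MAE/R² by default (a self-explanatory perfect fit would flatter
the statistics).

Non-declining chlorophyll series are flagged (`declining = FALSE`) rather
than rejected — a flat or rising plot is a data-quality signal the analyst
should see, not a crash.

## Whole-season integration

`interpolate_daily()` joins flight-date predictions linearly on a daily
calendar grid; `green_area_duration()` integrates by the trapezoidal rule,
which is exact for a piecewise-linear integrand (verified against a
fine-grid oracle at 1e-9, along with additivity over adjacent windows).
Integration starts at the first flight by default; an optional sowing
anchor prepends GAI 0 at the sowing date, since starting at sowing is the
other defensible convention — the flag makes the choice explicit.
`progressive_r2()` then traces how much of the final-biomass variance the
accumulating GAD explains at each date; the curve may legitimately
decline for models that destabilize during senescence.

## The synthetic-data generator

No field data ship with the package, so every stage is exercised on a
generator whose structure mirrors the study design the methods assume.

* **Reflectance forward model.** Per band, a Beer–Lambert two-endmember
  mixture \(R = R_{soil}e^{-k\,GAI} + R_{canopy}(1 - e^{-k\,GAI})\), with
  the extinction coefficient largest in red (0.90) and smallest in NIR
  (0.30). This is the minimal model that reproduces NDVI saturation above
  GAI ≈ 2–3 while the red-edge ratio keeps responding; it is a
  calibration device, not a radiative-transfer model (no PROSAIL-style
  leaf optics, no view-geometry effects, no soil moisture variation), so
  passing tests demonstrate internal consistency of the pipeline, not
  field accuracy of the shipped coefficients.
* **Irradiance and noise.** One log-normal factor (log-sd 0.08, a free
  parameter — the true per-date variability is unquantified) multiplies
  all bands of a date, mimicking the raw-band instability that ratios
  cancel; additive Gaussian noise (sd 0.004) represents sensor and
  extraction noise. Reflectance is clipped to (0, 1].
* **Seasonal GAI template.** A logistic rise to a per-plot maximum drawn
  uniformly from 3–7 m^2^ m^-2^, then a linear decline reaching exactly 0
  (ripeness), matching the sampled phenological range; 48 plots, 12 dates,
  4 cultivars by default.
* **Senescence trial.** Layered Weibull chlorophyll declines (scale
  1600 °C d, shape 9, chlorophyll 0.60 → 0.05 g m^-2^, four layers with
  area shares 0.40/0.30/0.20/0.10, lower layers senescing ~4 % earlier per
  layer), inverted through the SPAD calibration; generating parameters are
  attached for recovery tests.
* **Biomass.** Final biomass is β·GAD·(1 + ε) with β = 5 g m^-2^ per
  GAI-day, so the GAD–biomass correlation is recoverable and vanishes
  under permutation.
* **Determinism.** All randomness flows from one integer seed (default
  20170404); identical configurations reproduce byte-identical tables.

Problem sizes in the tests and analysis scripts (hundreds of records,
dozens of plots, grids of a few dozen points) were chosen as the smallest
sizes at which the statistical assertions are stable over the fixed
seeds.

## Numerical and interface choices

* Zonal extraction uses pixel-center containment (boundary pixels count
  as inside) and the convention that an even pixel count yields the mean
  of the two central values. Rasters are plain TIFF grids georeferenced by
  six-line world files; rotated affines are rejected, and a CRS mismatch
  between raster and polygon is an error naming both systems — no
  implicit reprojection.
* Nonpositive reflectance is flagged (`"nonpositive reflectance"`) and
  excluded with a logged count, never clamped: clamping would fabricate
  ratios.
* Rank-deficient OLS designs fail with the collinear terms named;
  exponential-fit non-convergence reports its start values.
* All tables are UTF-8 CSV with ISO-8601 dates; configuration is
  YAML/JSON merged over documented defaults, and the effective
  configuration is written next to a run's outputs.

## Known limitations

The shipped registry coefficients were calibrated on one sensor and one
crop; transferring them to another sensor's band set is not supported.
The generator does not emulate cultivar-specific reflectance (leaf angle,
single-leaf optics), mixed-pixel plot borders, cloud-shadow screening or
radiometric-target calibration — all upstream of this package's scope.
Senescence evaluation presumes a declining, roughly Weibull-shaped
chlorophyll trajectory; crops with strong regrowth violate it and are
flagged but not modelled.
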