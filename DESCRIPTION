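Package: gaiseason
Title: Whole-Season Green Area Index Prediction for Winter Wheat from
    Four-Band Multispectral Reflectance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calibration, comparison and whole-season application of green
    area index (GAI) models for winter wheat driven by four-band (green,
    red, red edge, NIR) multispectral reflectance. Ships the calibrated
    band-ratio models including the four-band VIQUO index and an
    exponential NDVI model, a date-grouped cross-validation harness for
    machine-learning comparators (PLS, SVM, KNN, MARS, boosted trees),
    error metrics broken down by GAI class, a chlorophyll-based canopy
    greenness procedure for evaluating predictions during senescence, and
    green-area-duration integration against final biomass. A synthetic
    data generator with a Beer-Lambert two-endmember forward model makes
    every stage testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    kernlab,
    caret,
    xgboost,
    mixOmics,
    jsonlite,
    yaml,
    pracma,
    rlang,
    withr
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
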