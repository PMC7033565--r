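#!/usr/bin/env Rscript
# Whole-season application: predict GAI for every flight of the season
# series, interpolate daily, integrate to green area duration (GAD) and
# relate it to final biomass — including the progressive R2 curve showing
# how the explained biomass variance builds up as flights accumulate.

library(gaiseason)

cfg <- run_config()
seas <- read_reflectance_csv("scratch/data/season_reflectance.csv")
biomass <- read_table_checked("scratch/data/final_biomass.csv",
                              c("plot_id", "biomass"),
                              numeric_cols = "biomass")

cal <- read_reflectance_csv("scratch/data/calibration_reflectance.csv")
cal$gai <- cal$gai_true
cal <- compute_predictors(apply_cleaning_filters(cal, cfg$cleaning_max_gai))
cal <- cal[cal$valid, ]

models <- list(
  VIQUO = fit_vi_model(cal, "ratio_linear",
                       c("nir_re", "nir_red", "nir_green")),
  NIR_RE = fit_vi_model(cal, "ratio_linear", "nir_re"),
  NDVI_exp = fit_vi_model(cal, "ndvi_exponential", "ndvi"))

gad_rows <- list(); r2_rows <- list()
for (nm in names(models)) {
  ser <- predict_season(seas, models[[nm]], model_name = nm)
  gad <- vapply(split(ser, ser$plot_id), function(s)
    green_area_duration(s$date, s$gai_pred), 1.0)
  gad_rows[[nm]] <- data.frame(plot_id = names(gad), model = nm, gad = gad)
  pr <- progressive_r2(ser, biomass)
  r2_rows[[nm]] <- cbind(model = nm, pr)
  message(sprintf("%-9s final GAD-biomass R2 = %.3f", nm,
                  pr$r2[nrow(pr)]))
}
write_table_csv(do.call(rbind, gad_rows), "results/green_area_duration.csv")
r2_tab <- do.call(rbind, r2_rows)
write_table_csv(r2_tab, "results/progressive_r2.csv")
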