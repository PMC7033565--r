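#!/usr/bin/env Rscript
# Resolve model error across the season: the seven-class GAI breakdown
# (MAE and relative MAE per observed-GAI class) for the selected models,
# plus the cultivar question — does adding the cultivar as a factor to a
# simple-ratio model improve it significantly?

library(gaiseason)

cfg <- run_config()
d <- read_reflectance_csv("scratch/data/calibration_reflectance.csv")
d$gai <- d$gai_true
d <- compute_predictors(apply_cleaning_filters(d, cfg$cleaning_max_gai))
d <- d[d$valid, ]
dates <- sort(unique(d$date))
eval_dates <- dates[seq(2, length(dates), by = 3)]
cal <- d[!d$date %in% eval_dates, ]
ev <- d[d$date %in% eval_dates, ]

scheme <- gai_class_scheme(cfg$class_breaks)
models <- list(
  NIR_RE = fit_vi_model(cal, "ratio_linear", "nir_re"),
  VIQUO = fit_vi_model(cal, "ratio_linear",
                       c("nir_re", "nir_red", "nir_green")),
  NDVI_exp = fit_vi_model(cal, "ndvi_exponential", "ndvi"))

bd <- do.call(rbind, lapply(names(models), function(nm) {
  b <- class_breakdown(predict_gai(models[[nm]], ev), ev$gai, scheme)
  cbind(model = nm, b)
}))
print(bd, digits = 3)
write_table_csv(bd, "results/class_breakdown.csv")

# cultivar common vs extended model on the simple-ratio predictor
d$role <- ifelse(d$date %in% eval_dates, "evaluation", "calibration")
cc <- cultivar_model_comparison(d, predictor_spec = "nir_re")
message(sprintf(paste0("common model MAE cal/eval: %.3f/%.3f; extended: ",
                       "%.3f/%.3f; cultivar ANOVA p = %.3f"),
                cc$mae_common_cal, cc$mae_common_eval, cc$mae_extended_cal,
                cc$mae_extended_eval, cc$anova_p))
write_table_csv(as.data.frame(cc), "results/cultivar_comparison.csv")
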