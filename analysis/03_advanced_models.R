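#!/usr/bin/env Rscript
# Compare machine-learning regressors against the VI models under the same
# date-grouped splits: tuning by grid search, parameter selection by
# cross-validated RMSE where the hold-out sample is always a whole date.
# Grids are kept small; they are config-overridable in the package API.

library(gaiseason)

cfg <- run_config()
d <- read_reflectance_csv("scratch/data/calibration_reflectance.csv")
d$gai <- d$gai_true
d <- apply_cleaning_filters(d, max_gai = cfg$cleaning_max_gai)
d <- compute_predictors(d)
d <- d[d$valid, ]

dates <- sort(unique(d$date))
eval_dates <- dates[seq(2, length(dates), by = 3)]
cal <- d[!d$date %in% eval_dates, ]
ev <- d[d$date %in% eval_dates, ]
k <- min(cfg$cv_folds, length(unique(cal$date)))
folds <- date_grouped_folds(cal$date, k = k, seed = cfg$seed)
message("date-grouped CV with k = ", k)

grids <- list(
  pls = data.frame(ncomp = 1:3),
  svm_linear = data.frame(cost = c(0.25, 1, 4)),
  svm_radial = expand.grid(cost = c(0.5, 2), sigma = c(0.25, 1)),
  knn = data.frame(k = c(3, 5, 9)),
  mars = data.frame(degree = 1:2),
  boosted_trees = expand.grid(depth = 1:2, trees = c(100, 300)))

rows <- lapply(names(grids), function(fam) {
  m <- fit_advanced_model(cal, fam, folds, tuning_grid = grids[[fam]],
                          seed = cfg$seed)
  e_cal <- error_metrics(predict_gai(m, cal), cal$gai)
  e_ev <- error_metrics(predict_gai(m, ev), ev$gai)
  sel <- m$provenance$cv_table[m$provenance$selected, , drop = FALSE]
  data.frame(model = fam,
             selected = paste(names(m$parameters),
                              unlist(m$parameters), sep = "=",
                              collapse = ","),
             cv_rmse = sel$rmse,
             mae_cal = e_cal$mae, rmse_cal = e_cal$rmse,
             mae_eval = e_ev$mae, rmse_eval = e_ev$rmse)
})
tab <- do.call(rbind, rows)
print(tab, digits = 3)
write_table_csv(tab, "results/advanced_model_comparison.csv")
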