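test_that("registry models reproduce the published calibration equations", {
  reg <- gai_registry()
  expect_setequal(names(reg),
                  c("NIR_RE", "NIR_Red", "NIR_Green", "VIQUO",
                    "VIQUO_interaction", "NDVI_exp"))
  zero <- data.frame(nir_re = 0, nir_red = 0, nir_green = 0, ndvi = 0)
  # intercepts at predictor value zero, to all printed digits
  expect_identical(predict_gai(reg$VIQUO, zero), -2.829243)
  expect_identical(predict_gai(reg$NIR_RE, zero), -5.498)
  expect_identical(predict_gai(reg$NIR_Red, zero), -0.2066)
  expect_identical(predict_gai(reg$NIR_Green, zero), -1.023)
  expect_identical(predict_gai(reg$NDVI_exp, zero), 0.00197)
  # hand-summed four-ratio model at (1,1,1)
  one <- data.frame(nir_re = 1, nir_red = 1, nir_green = 1)
  expect_equal(predict_gai(reg$VIQUO, one), -0.698131, tolerance = 1e-12)
})

test_that("registry prediction equals manual equation evaluation", {
  reg <- gai_registry()
  p <- random_predictors(1000, seed = 11)
  expect_equal(predict_gai(reg$VIQUO, p), eval_viquo_manually(p),
               tolerance = 1e-12)
  expect_equal(predict_gai(reg$NIR_RE, p), -5.498 + 4.64 * p$nir_re,
               tolerance = 1e-12)
  expect_equal(predict_gai(reg$NDVI_exp, p),
               0.00197 * exp(8.42847 * p$ndvi), tolerance = 1e-12)
  # 8-term interaction expansion
  manual5 <- 0.23558 - 0.72441 * p$nir_re + 0.11783 * p$nir_red -
    0.02023 * p$nir_green + 0.01313 * p$nir_red * p$nir_green +
    0.10864 * p$nir_red * p$nir_re + 0.28252 * p$nir_re * p$nir_green -
    0.01195 * p$nir_re * p$nir_green * p$nir_red
  expect_equal(predict_gai(reg$VIQUO_interaction, p), manual5,
               tolerance = 1e-12)
})

test_that("prediction demands every declared predictor and keeps negatives", {
  reg <- gai_registry()
  expect_error(predict_gai(reg$VIQUO, data.frame(nir_re = 1, nir_red = 1)),
               "nir_green")
  low <- data.frame(nir_re = 1)  # NIR/RE of 1 -> negative prediction
  expect_lt(predict_gai(reg$NIR_RE, low), 0)
  expect_identical(predict_gai(reg$NIR_RE, low, clip_at_zero = TRUE), 0)
})

test_that("OLS refit recovers generating coefficients exactly at zero noise", {
  p <- random_predictors(300, seed = 5)
  d1 <- data.frame(nir_re = p$nir_re, gai = -5.498 + 4.64 * p$nir_re)
  m1 <- fit_vi_model(d1, "ratio_linear", predictor_spec = "nir_re")
  expect_equal(unname(m1$parameters$coef), c(-5.498, 4.64), tolerance = 1e-8)

  d4 <- cbind(p, gai = eval_viquo_manually(p))
  m4 <- fit_vi_model(d4, "ratio_linear")
  expect_equal(unname(m4$parameters$coef),
               c(-2.829243, 1.814068, -0.004532, 0.321576), tolerance = 1e-8)

  # constant response: zero slopes, intercept equals the constant
  dc <- cbind(p, gai = 3.3)
  mc <- fit_vi_model(dc, "ratio_linear")
  expect_equal(unname(mc$parameters$coef), c(3.3, 0, 0, 0), tolerance = 1e-10)
})

test_that("exponential NDVI fit recovers its generating parameters", {
  withr::with_seed(9, {
    x <- runif(250, 0, 0.95)
  })
  d <- data.frame(ndvi = x, gai = 0.002 * exp(8.4 * x))
  m <- fit_vi_model(d, "ndvi_exponential", predictor_spec = "ndvi")
  expect_equal(m$parameters$a, 0.002, tolerance = 1e-6)
  expect_equal(m$parameters$b, 8.4, tolerance = 1e-6)
})

test_that("rank-deficient designs are rejected with the collinear term named", {
  p <- random_predictors(50, seed = 2)
  p$dup <- p$nir_re
  d <- cbind(p, gai = p$nir_re * 2)
  expect_error(fit_vi_model(d, "ratio_linear",
                            predictor_spec = c("nir_re", "dup")),
               "collinear.*dup")
})

test_that("date-grouped folds partition dates and never split one", {
  dates <- rep(paste0("2018-05-", 10:19), each = 4)
  f <- date_grouped_folds(dates, k = 10, seed = 3)
  expect_equal(as.vector(table(f$fold)), rep(1L, 10))  # one date per fold
  per_record <- gaiseason:::fold_of(f, dates)
  expect_true(all(tapply(per_record, dates, function(x) length(unique(x))) == 1))
  expect_error(date_grouped_folds(rep(paste0("d", 1:5), 3), k = 10),
               "5.*10|fewer")
})

test_that("a single grid point reduces to a direct fit with a one-row CV table", {
  d <- linear_gai_data()
  folds <- date_grouped_folds(d$date, k = 3, seed = 1)
  m <- fit_advanced_model(d, "knn", folds, tuning_grid = data.frame(k = 3),
                          seed = 1)
  expect_equal(nrow(m$provenance$cv_table), 1)
  expect_true(is.finite(m$provenance$cv_table$rmse))
})

test_that("linear SVM matches the linear oracle on noiseless linear data", {
  d <- linear_gai_data(n_per_date = 15)
  folds <- date_grouped_folds(d$date, k = 3, seed = 1)
  m <- fit_advanced_model(d, "svm_linear", folds,
                          tuning_grid = data.frame(cost = c(1, 4)), seed = 1)
  held <- linear_gai_data(n_per_date = 20, seed = 99)
  pred <- predict_gai(m, held)
  expect_lt(mean(abs(pred - held$gai)), 0.05)
})

test_that("boosted trees refuse degenerate node-size settings", {
  d <- linear_gai_data(n_per_date = 2, dates = c("2018-04-01", "2018-05-01",
                                                 "2018-06-01"))
  folds <- date_grouped_folds(d$date, k = 3, seed = 1)
  expect_error(fit_advanced_model(d, "boosted_trees", folds,
                                  tuning_grid = data.frame(depth = 1, trees = 10)),
               "10")
})

test_that("every advanced family fits and predicts on a small dataset", {
  d <- linear_gai_data(n_per_date = 12, noise_sd = 0.1)
  folds <- date_grouped_folds(d$date, k = 3, seed = 2)
  grids <- list(pls = data.frame(ncomp = 1:2),
                svm_radial = data.frame(cost = 1, sigma = 0.5),
                mars = data.frame(degree = 1),
                boosted_trees = data.frame(depth = 2, trees = 60))
  for (fam in names(grids)) {
    m <- fit_advanced_model(d, fam, folds, tuning_grid = grids[[fam]],
                            seed = 4)
    pred <- predict_gai(m, d)
    expect_true(all(is.finite(pred)), info = fam)
    expect_lt(mean(abs(pred - d$gai)), 2, label = paste(fam, "MAE"))
  }
})

test_that("centering and scaling statistics come from the training split only", {
  # two dates with very different predictor locations: leaky scaling
  # (computed on all rows) changes held-out predictions for KNN
  d <- data.frame(
    nir_re = c(1.0, 1.1, 1.2, 1.3, 9.0, 9.1, 9.2, 9.3),
    nir_red = c(2.0, 2.1, 2.2, 2.3, 30.0, 30.1, 30.2, 30.3),
    nir_green = c(1.5, 1.6, 1.7, 1.8, 8.0, 8.1, 8.2, 8.3),
    date = rep(as.Date(c("2018-05-01", "2018-06-01")), each = 4))
  d$gai <- c(1, 1, 1, 1, 5, 5, 5, 5)
  folds <- date_grouped_folds(d$date, k = 2, seed = 1)
  m <- fit_advanced_model(d, "knn", folds, tuning_grid = data.frame(k = 1),
                          seed = 1)
  # independent oracle: per fold, scale train with train stats only,
  # 1-NN prediction for the held-out date
  X <- as.matrix(d[, c("nir_re", "nir_red", "nir_green")])
  f <- gaiseason:::fold_of(folds, d$date)
  resid_clean <- unlist(lapply(unique(f), function(k) {
    tr <- f != k
    mu <- colMeans(X[tr, ]); s <- apply(X[tr, ], 2, sd)
    Ztr <- scale(X[tr, ], mu, s); Zte <- scale(X[!tr, ], mu, s)
    pred <- apply(Zte, 1, function(z) {
      d$gai[tr][which.min(colSums((t(Ztr) - z)^2))]
    })
    pred - d$gai[!tr]
  }))
  expect_equal(m$provenance$cv_table$rmse, sqrt(mean(resid_clean^2)),
               tolerance = 1e-10)
  # the final model's preprocessing uses all data (fitting is over), but
  # per-fold statistics must differ from the global ones on this dataset
  expect_false(isTRUE(all.equal(colMeans(X[f != 1, ]), colMeans(X))))
})
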