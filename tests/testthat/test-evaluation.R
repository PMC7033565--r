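test_that("error metrics match their closed forms", {
  expect_equal(error_metrics(1:5, 1:5), list(mae = 0, rmse = 0))
  m <- error_metrics(c(1, -1), c(0, 0))
  expect_equal(m$mae, 1); expect_equal(m$rmse, 1)
  m2 <- error_metrics(c(0, 2), c(0, 0))
  expect_equal(m2$mae, 1); expect_equal(m2$rmse, sqrt(2))
  expect_error(error_metrics(numeric(0), numeric(0)), "empty")
  expect_error(error_metrics(1:3, 1:2), "length")
})

test_that("the default scheme has seven classes and assigns boundaries left-closed", {
  sch <- gai_class_scheme()
  expect_length(sch$labels, 7)
  cls <- classify_gai(c(0, 0.1, 0.25, 1.9, 2, 3.5, 4, 5, 8), sch)
  expect_equal(as.character(cls),
               c("DeadPlant", "(0,0.25)", "[0.25,2)", "[0.25,2)", "[2,3)",
                 "[3,4)", "[4,5)", ">=5", ">=5"))
})

test_that("per-class breakdown computes rMAE and leaves it NA at zero mean", {
  # all observed zero -> DeadPlant only, rmae undefined
  b0 <- class_breakdown(c(0.1, -0.2, 0), c(0, 0, 0))
  expect_equal(b0$n[b0$class == "DeadPlant"], 3)
  expect_true(is.na(b0$rmae[b0$class == "DeadPlant"]))
  expect_false(is.na(b0$mae[b0$class == "DeadPlant"]))
  # rmae is NA exactly for the zero-mean class
  expect_identical(is.na(b0$rmae), b0$n == 0 | b0$class == "DeadPlant")

  # a single populated class reproduces the global MAE
  obs <- runif(20, 2.2, 2.8)
  pred <- obs + rnorm(20, sd = 0.3)
  b1 <- class_breakdown(pred, obs)
  expect_equal(b1$mae[b1$class == "[2,3)"], error_metrics(pred, obs)$mae)

  # definition arithmetic: mean 4, mae 0.64 -> rmae 0.16
  obs2 <- c(3.8, 4.2); pred2 <- obs2 + c(0.64, -0.64)
  b2 <- class_breakdown(pred2, obs2)
  expect_equal(b2$rmae[b2$class == "[3,4)" | b2$class == "[4,5)"],
               c(0.64 / 3.8, 0.64 / 4.2))
})

test_that("n-weighted class MAEs recombine to the global MAE", {
  for (i in 1:50) {
    n <- 30 + i
    obs <- withr::with_seed(i, c(rep(0, 3), runif(n, 0, 7)))
    pred <- withr::with_seed(i + 1000, obs + rnorm(n + 3, sd = 0.5))
    b <- class_breakdown(pred, obs)
    pop <- b$n > 0
    expect_equal(sum(b$n[pop] * b$mae[pop]) / sum(b$n[pop]),
                 error_metrics(pred, obs)$mae, tolerance = 1e-12)
  }
})

test_that("rMAE is unit-free", {
  obs <- withr::with_seed(4, runif(40, 0.3, 6))
  pred <- obs + withr::with_seed(5, rnorm(40, sd = 0.4))
  # rescaling both series rescales class membership too; compare via a
  # one-class scheme so the same rows stay together
  sch <- gai_class_scheme(breaks = c(0, Inf))
  r1 <- class_breakdown(pred, obs, sch)
  r2 <- class_breakdown(pred * 3.7, obs * 3.7, sch)
  expect_equal(r2$rmae[2], r1$rmae[2], tolerance = 1e-12)
})

test_that("error increase is a plain percentage with a guarded denominator", {
  expect_equal(error_increase(0.35, 0.45), 100 * 0.1 / 0.35)
  expect_equal(error_increase(0.5, 0.5), 0)
  expect_error(error_increase(0, 0.4), "> 0")
})

test_that("cleaning filter drops strictly-above-threshold rows and is idempotent", {
  d <- data.frame(plot = letters[1:3], gai = c(6.9, 7.0, 7.1))
  suppressMessages(f <- apply_cleaning_filters(d))
  expect_equal(f$gai, c(6.9, 7.0))  # boundary kept
  expect_equal(attr(f, "exclusion_log")$plot, "c")
  f2 <- apply_cleaning_filters(f)
  expect_equal(f2$gai, f$gai)
  expect_equal(nrow(attr(f2, "exclusion_log")), 0)

  d2 <- data.frame(gai = runif(10, 0, 6))
  d2$gai[c(2, 5, 9)] <- 8
  suppressMessages(f3 <- apply_cleaning_filters(d2))
  expect_equal(nrow(f3), 7)
})

test_that("extended cultivar model never fits worse than the common one", {
  d <- linear_gai_data(n_per_date = 10, noise_sd = 0.3)
  d$cultivar <- rep_len(c("Piko", "Solehio"), nrow(d))
  d$role <- ifelse(d$date <= as.Date("2018-06-01"), "calibration",
                   "evaluation")
  res <- cultivar_model_comparison(d, predictor_spec = "nir_re")
  # least-squares nesting guarantees the RMSE ordering on the fit split
  # (the analogous MAE ordering is not a theorem and can invert)
  expect_lte(res$rmse_extended_cal, res$rmse_common_cal + 1e-12)
  expect_true(is.finite(res$mae_extended_cal) && is.finite(res$mae_common_cal))
  expect_true(res$anova_p >= 0 && res$anova_p <= 1)
  d$cultivar <- "only_one"
  expect_error(cultivar_model_comparison(d), "2 cultivars")
})

test_that("the cultivar ANOVA holds its type-I error and detects real effects", {
  sim_once <- function(seed, effect) {
    withr::with_seed(seed, {
      n <- 60
      d <- data.frame(nir_re = runif(n, 1, 3),
                      cultivar = rep_len(c("A", "B"), n),
                      date = rep_len(as.Date("2018-05-01") + 0:5, n))
      noise_sd <- 0.3
      d$gai <- -1 + 2 * d$nir_re + ifelse(d$cultivar == "B", effect, 0) +
        rnorm(n, sd = noise_sd)
      d$role <- "calibration"
      cultivar_model_comparison(d, predictor_spec = "nir_re")$anova_p
    })
  }
  # type I error at the nominal 5% level (no cultivar effect simulated)
  p_null <- vapply(1:500, sim_once, 1.0, effect = 0)
  expect_gt(mean(p_null < 0.05), 0.03)
  expect_lt(mean(p_null < 0.05), 0.07)
  # power: intercept shift of 5 x noise sd is essentially always found
  p_alt <- vapply(1:200, sim_once, 1.0, effect = 5 * 0.3)
  expect_gte(mean(p_alt < 0.05), 0.95)
})
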