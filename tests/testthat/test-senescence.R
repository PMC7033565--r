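test_that("SPAD conversion follows the exponential calibration", {
  expect_equal(spad_to_chl(40, c(a = 0.05, b = 0.03)), 0.05 * exp(1.2))
  # b = 0 degenerates to the constant a
  expect_equal(spad_to_chl(c(10, 50), c(a = 0.04, b = 0)), c(0.04, 0.04))
  # strictly increasing for b > 0
  chl <- spad_to_chl(c(20, 30, 45), c(a = 0.05, b = 0.03))
  expect_true(all(diff(chl) > 0))
  expect_error(spad_to_chl(40), "calibration")
})

test_that("canopy chlorophyll is the area-weighted layer sum", {
  expect_equal(canopy_chlorophyll(c(2, 2, 2), c(0.5, 0.3, 0.2)), 2)
  expect_equal(canopy_chlorophyll(c(1, 3), c(0.5, 0.5)), 2)
  expect_error(canopy_chlorophyll(c(1, 3), c(0.5, 0.3)), "0.8")
})

test_that("Weibull greenness fit recovers noiseless generating parameters", {
  tt <- seq(1200, 2100, by = 60)
  truth <- list(hi = 0.62, lo = 0.06, scale = 1650, shape = 8.5)
  chl <- truth$lo + (truth$hi - truth$lo) * exp(-(tt / truth$scale)^truth$shape)
  cv <- fit_greenness(tt, chl)
  for (p in names(truth)) {
    expect_equal(cv$parameters[[p]], truth[[p]], tolerance = 1e-4,
                 label = p)
  }
  # normalization identity: 1 at the curve's maximum (thermal time 0),
  # 0 at its asymptotic minimum far beyond the scale
  expect_equal(greenness_at(cv, 0), 1, tolerance = 1e-12)
  expect_lt(abs(greenness_at(cv, 3 * truth$scale)), 1e-6)
})

test_that("greenness is invariant to a constant chlorophyll offset", {
  tt <- seq(1200, 2100, by = 50)
  chl <- 0.05 + 0.55 * exp(-(tt / 1600)^9) +
    withr::with_seed(2, rnorm(length(tt), sd = 0.005))
  a <- fit_greenness(tt, chl, seed = 3)
  b <- fit_greenness(tt, chl + 0.4, seed = 3)
  expect_equal(b$measured_greenness, a$measured_greenness, tolerance = 1e-4)
  # monotone fitted curve implies monotone greenness
  expect_true(all(diff(a$fitted_greenness) <= 1e-12))
})

test_that("degenerate greenness inputs are rejected or flagged", {
  expect_error(fit_greenness(1:4, c(4, 3, 2, 1)), "5 time points")
  expect_error(fit_greenness(c(1, 1, 2, 3, 4), rep(1, 5)), "increasing")
  rising <- fit_greenness(seq(100, 900, by = 100),
                          0.1 + 0.5 * (1 - exp(-(seq(100, 900, by = 100) / 500)^3)))
  expect_false(rising$diagnostics$declining)
})

test_that("predicted greenness is prediction relative to the onset value", {
  d <- as.Date("2017-06-19") + c(0, 5, 10, 15)
  g <- c(4, 3, 2, 1)
  pg <- predicted_greenness(d, g, as.Date("2017-06-19"))
  expect_equal(pg$greenness, c(1, 0.75, 0.5, 0.25))
  expect_equal(pg$greenness[1], 1)
  expect_error(predicted_greenness(d, c(0, 3, 2, 1), d[1]), "> 0")
  expect_error(predicted_greenness(d, g, as.Date("2017-06-18")), "onset")
})

test_that("greenness agreement excludes the self-evident onset date", {
  d <- as.Date("2017-06-19") + seq(0, 36, by = 4)
  meas <- data.frame(date = d, greenness = seq(1, 0.1, length.out = 10))
  pred <- meas
  a <- greenness_agreement(meas, pred)
  expect_equal(a$mae, 0); expect_equal(a$r2, 1)
  expect_equal(a$n, 9)  # onset dropped
  pred_off <- transform(pred, greenness = greenness + 0.1)
  a2 <- greenness_agreement(meas, pred_off)
  expect_equal(a2$mae, 0.1, tolerance = 1e-12)
  expect_equal(a2$r2, 1, tolerance = 1e-12)
  expect_error(greenness_agreement(meas[1:2, ], pred[1:2, ]), "2 common")
})

test_that("independent random greenness series share no systematic correlation", {
  r2 <- vapply(1:500, function(i) {
    withr::with_seed(i, {
      d <- data.frame(date = 1:10, greenness = runif(10))
      p <- data.frame(date = 1:10, greenness = runif(10))
    })
    greenness_agreement(d, p, exclude_onset = FALSE)$r2
  }, 1.0)
  expect_lt(mean(r2), 0.25)
})

test_that("the full SPAD pipeline recovers the true normalized trajectory", {
  cfg <- senescence_sim_config(n_plots = 3, noise_sd = 0)
  tr <- generate_spad_trial(cfg)
  curves <- fit_greenness_trial(tr, cfg$spad_calibration, seed = 1)
  truth <- attr(tr, "truth")
  for (pid in names(curves)) {
    cv <- curves[[pid]]
    # true canopy chlorophyll: area-weighted mix of the layer curves
    tl <- truth[truth$plot_id == pid, ]
    true_canopy <- rowSums(vapply(seq_len(nrow(tl)), function(i) {
      cfg$layer_area_fractions[tl$layer[i]] *
        gaiseason:::weibull_decline(cv$thermal_time, tl$chl_max[i],
                                    tl$chl_min[i], tl$scale[i], tl$shape[i])
    }, numeric(length(cv$thermal_time))))
    # the layer mix shares the asymptotes chl_max (t = 0) and chl_min,
    # which are the normalization constants of the true curve
    true_norm <- (true_canopy - cfg$chl_min) / (cfg$chl_max - cfg$chl_min)
    expect_lt(mean(abs(cv$measured_greenness - true_norm)), 0.02)
  }
})
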