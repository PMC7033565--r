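# Shared fixtures, built in code at test time.

# Random but positive predictor sets (band ratios and NDVI).
random_predictors <- function(n, seed = 1) {
  withr::with_seed(seed, data.frame(
    nir_re = runif(n, 0.8, 4),
    nir_red = runif(n, 1, 25),
    nir_green = runif(n, 1, 10),
    ndvi = runif(n, 0, 0.95)))
}

# Random four-band reflectance records.
random_records <- function(n, seed = 1) {
  withr::with_seed(seed, data.frame(
    green = runif(n, 0.02, 0.15),
    red = runif(n, 0.02, 0.12),
    red_edge = runif(n, 0.1, 0.4),
    nir = runif(n, 0.15, 0.6)))
}

# Manual evaluation of the four-ratio linear equation (independent of
# predict_gai's term-parsing path).
eval_viquo_manually <- function(p) {
  -2.829243 + 1.814068 * p$nir_re - 0.004532 * p$nir_red +
    0.321576 * p$nir_green
}

# Exactly linear GAI data on a set of dates, for CV/learner tests.
linear_gai_data <- function(n_per_date = 12, dates = paste0("2018-0", 4:9, "-01"),
                            seed = 7, noise_sd = 0) {
  withr::with_seed(seed, {
    d <- do.call(rbind, lapply(dates, function(dt) {
      p <- data.frame(nir_re = runif(n_per_date, 0.8, 4),
                      nir_red = runif(n_per_date, 1, 25),
                      nir_green = runif(n_per_date, 1, 10))
      p$date <- as.Date(dt)
      p
    }))
    d$gai <- 1 + 2 * d$nir_re - 0.1 * d$nir_red + 0.5 * d$nir_green +
      rnorm(nrow(d), sd = noise_sd)
    d
  })
}
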