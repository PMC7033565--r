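#' Forward-model configuration for synthetic reflectance data
#'
#' Defines the generative model used by [generate_calibration_set()] and
#' [generate_season()]. Per band, reflectance follows a Beer-Lambert
#' two-endmember mixture between bare soil and a closed canopy,
#' \deqn{R(GAI) = R_{soil} e^{-k \cdot GAI} + R_{canopy} (1 - e^{-k \cdot GAI}),}
#' multiplied by a per-date log-normal irradiance factor shared by all bands
#' of a date (so band ratios cancel it) and perturbed by additive Gaussian
#' noise. The extinction coefficients are largest in the red, which
#' reproduces the well-documented saturation of NDVI above a GAI of roughly
#' 2-3 m^2 m^-2, while the red-edge and NIR bands keep responding in dense
#' canopies.
#'
#' @param soil_reflectance,canopy_reflectance named numeric vectors with
#'   fractional reflectance (0-1) for bands `green`, `red`, `red_edge`,
#'   `nir` of bare soil and of an asymptotically dense canopy.
#' @param k_band named numeric vector of per-band extinction coefficients
#'   (unitless, > 0).
#' @param irradiance_sd standard deviation, on the log scale, of the
#'   per-date multiplicative irradiance factor.
#' @param noise_sd standard deviation of additive reflectance noise.
#' @param gai_range numeric length-2, attainable GAI range in m^2 m^-2
#'   (within \[0, 10\]).
#' @param n_plots,n_dates,n_cultivars trial dimensions.
#' @param biomass_beta proportionality constant between green area duration
#'   (m^2 m^-2 d) and final biomass (g m^-2) used by [generate_season()].
#' @param seed integer root seed; all randomness of the generators flows
#'   from it.
#'
#' @return an object of class `forward_model_config`.
#' @export
forward_model_config <- function(soil_reflectance = c(green = 0.08, red = 0.10,
                                                      red_edge = 0.13, nir = 0.16),
                                 canopy_reflectance = c(green = 0.10, red = 0.04,
                                                        red_edge = 0.35, nir = 0.55),
                                 k_band = c(green = 0.55, red = 0.90,
                                            red_edge = 0.40, nir = 0.30),
                                 irradiance_sd = 0.08,
                                 noise_sd = 0.004,
                                 gai_range = c(0, 7),
                                 n_plots = 48,
                                 n_dates = 12,
                                 n_cultivars = 4,
                                 biomass_beta = 5,
                                 seed = 20170404) {
  cfg <- list(soil_reflectance = soil_reflectance,
              canopy_reflectance = canopy_reflectance,
              k_band = k_band,
              irradiance_sd = irradiance_sd,
              noise_sd = noise_sd,
              gai_range = gai_range,
              n_plots = n_plots,
              n_dates = n_dates,
              n_cultivars = n_cultivars,
              biomass_beta = biomass_beta,
              seed = seed)
  class(cfg) <- "forward_model_config"
  validate_forward_config(cfg)
  cfg
}

.bands <- c("green", "red", "red_edge", "nir")

validate_forward_config <- function(cfg) {
  for (fld in c("soil_reflectance", "canopy_reflectance")) {
    v <- cfg[[fld]]
    if (!all(.bands %in% names(v)) || any(!is.finite(v)) ||
        any(v < 0) || any(v > 1)) {
      stop("invalid configuration field '", fld,
           "': need finite reflectances in [0,1] for bands ",
           paste(.bands, collapse = ", "), call. = FALSE)
    }
  }
  if (!all(.bands %in% names(cfg$k_band)) || any(cfg$k_band <= 0)) {
    stop("invalid configuration field 'k_band': coefficients must be > 0",
         call. = FALSE)
  }
  if (length(cfg$gai_range) != 2 || cfg$gai_range[1] < 0 ||
      cfg$gai_range[2] > 10 || diff(cfg$gai_range) <= 0) {
    stop("invalid configuration field 'gai_range': must lie within [0, 10]",
         call. = FALSE)
  }
  for (fld in c("irradiance_sd", "noise_sd")) {
    if (!is.numeric(cfg[[fld]]) || cfg[[fld]] < 0) {
      stop("invalid configuration field '", fld, "': must be >= 0",
           call. = FALSE)
    }
  }
  for (fld in c("n_plots", "n_dates", "n_cultivars")) {
    if (cfg[[fld]] < 1 || cfg[[fld]] != round(cfg[[fld]])) {
      stop("invalid configuration field '", fld,
           "': must be a positive integer", call. = FALSE)
    }
  }
  invisible(cfg)
}

#' Noiseless forward reflectance for a GAI value
#'
#' Evaluates the Beer-Lambert two-endmember mixture of a
#' [forward_model_config()] without irradiance or noise terms. Used by the
#' generators and available directly for sensitivity analyses (e.g.
#' differencing NDVI along a GAI grid to quantify saturation).
#'
#' @param gai numeric vector of GAI values (m^2 m^-2).
#' @param config a `forward_model_config`.
#' @return data.frame with one row per `gai` value and columns `green`,
#'   `red`, `red_edge`, `nir`.
#' @export
forward_reflectance <- function(gai, config = forward_model_config()) {
  stopifnot(inherits(config, "forward_model_config"))
  out <- lapply(.bands, function(b) {
    w <- exp(-config$k_band[[b]] * gai)
    config$soil_reflectance[[b]] * w + config$canopy_reflectance[[b]] * (1 - w)
  })
  names(out) <- .bands
  as.data.frame(out)
}

# Seasonal GAI template on normalized season time t in [0, 1]: logistic rise
# to the plot maximum, then linear decline reaching exactly 0 at t = 1
# (ripening complete / dead plant).
gai_season_template <- function(t, gai_max, t_mid = 0.3, rate = 14, t_peak = 0.55) {
  n <- max(length(t), length(gai_max))
  t <- rep_len(t, n); gai_max <- rep_len(gai_max, n)
  rise <- gai_max / (1 + exp(-rate * (pmin(t, t_peak) - t_mid)))
  peak_val <- gai_max / (1 + exp(-rate * (t_peak - t_mid)))
  decline <- peak_val * (1 - (t - t_peak) / (1 - t_peak))
  ifelse(t <= t_peak, rise, pmax(decline, 0))
}

.make_plot_frame <- function(config) {
  plot_id <- sprintf("P%03d", seq_len(config$n_plots))
  cultivar <- paste0("cv", ((seq_len(config$n_plots) - 1L) %% config$n_cultivars) + 1L)
  data.frame(plot_id = plot_id, cultivar = cultivar, stringsAsFactors = FALSE)
}

.observe_reflectance <- function(gai, date_factor, config) {
  refl <- forward_reflectance(gai, config)
  n <- nrow(refl)
  for (b in .bands) {
    obs <- refl[[b]] * date_factor + rnorm(n, sd = config$noise_sd)
    refl[[b]] <- pmin(pmax(obs, 1e-6), 1)  # clip to (0, 1]
  }
  refl
}

#' Generate a synthetic GAI calibration set
#'
#' Simulates a plot x date reflectance trial with known ("destructively
#' sampled") GAI. Each plot follows a seasonal GAI template rising
#' logistically to a per-plot maximum drawn uniformly from 3-7 m^2 m^-2 and
#' declining linearly to 0; band reflectance is produced by the forward
#' model of `config` with a per-date shared irradiance factor and additive
#' noise.
#'
#' @param config a [forward_model_config()].
#' @param start_date first flight date (the dates are weekly from here).
#' @return data.frame with columns `plot_id`, `date`, `cultivar`, `green`,
#'   `red`, `red_edge`, `nir`, `gai_true`.
#' @export
generate_calibration_set <- function(config = forward_model_config(),
                                     start_date = as.Date("2017-04-04")) {
  validate_forward_config(config)
  set.seed(config$seed)
  plots <- .make_plot_frame(config)
  dates <- start_date + round(seq(0, 126, length.out = config$n_dates))
  t_norm <- seq(0, 1, length.out = config$n_dates)
  gai_max <- runif(config$n_plots, min = max(3, config$gai_range[1]),
                   max = config$gai_range[2])
  date_factor <- exp(rnorm(config$n_dates, sd = config$irradiance_sd))

  out <- vector("list", config$n_dates)
  for (d in seq_len(config$n_dates)) {
    gai <- gai_season_template(t_norm[d], gai_max)
    refl <- .observe_reflectance(gai, date_factor[d], config)
    out[[d]] <- data.frame(plot_id = plots$plot_id, date = dates[d],
                           cultivar = plots$cultivar, refl,
                           gai_true = gai, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate a synthetic whole-season overflight series with final biomass
#'
#' Emulates the repeated-overflight design used to evaluate whole-season
#' GAI prediction: each plot is observed at every flight date, and final
#' biomass is proportional to the plot's true green area duration (GAD, the
#' time integral of GAI), `biomass = beta * GAD * (1 + noise)`, so the
#' GAD-biomass correlation is recoverable downstream.
#'
#' @param config a [forward_model_config()].
#' @param flights Date vector of at least two flight dates.
#' @param biomass_noise_sd relative (multiplicative) noise sd on final
#'   biomass; 0 gives an exact linear GAD-biomass relation.
#' @return list with elements `reflectance` (plot x flight table with true
#'   GAI) and `biomass` (`plot_id`, `biomass` in g m^-2, plus the true
#'   `gad`).
#' @export
generate_season <- function(config = forward_model_config(),
                            flights = as.Date("2018-04-04") + round(seq(0, 104, length.out = 14)),
                            biomass_noise_sd = 0.05) {
  validate_forward_config(config)
  flights <- sort(as.Date(flights))
  if (length(flights) < 2) {
    stop("at least two flight dates are required", call. = FALSE)
  }
  set.seed(config$seed + 1L)
  plots <- .make_plot_frame(config)
  span <- as.numeric(max(flights) - min(flights))
  t_norm <- as.numeric(flights - min(flights)) / span
  gai_max <- runif(config$n_plots, min = max(3, config$gai_range[1]),
                   max = config$gai_range[2])
  date_factor <- exp(rnorm(length(flights), sd = config$irradiance_sd))

  out <- vector("list", length(flights))
  gai_mat <- matrix(0, config$n_plots, length(flights))
  for (d in seq_along(flights)) {
    gai <- gai_season_template(t_norm[d], gai_max)
    gai_mat[, d] <- gai
    refl <- .observe_reflectance(gai, date_factor[d], config)
    out[[d]] <- data.frame(plot_id = plots$plot_id, date = flights[d],
                           cultivar = plots$cultivar, refl,
                           gai_true = gai, stringsAsFactors = FALSE)
  }
  refl_tab <- do.call(rbind, out)
  rownames(refl_tab) <- NULL

  days <- as.numeric(flights - min(flights))
  gad <- apply(gai_mat, 1, function(g) pracma::trapz(days, g))
  biomass <- config$biomass_beta * gad *
    (1 + rnorm(config$n_plots, sd = biomass_noise_sd))
  list(reflectance = refl_tab,
       biomass = data.frame(plot_id = plots$plot_id, gad = gad,
                            biomass = biomass, stringsAsFactors = FALSE))
}

#' Senescence-trial simulation configuration
#'
#' Parameters of the synthetic SPAD trial generated by
#' [generate_spad_trial()]. Per plot and leaf layer, chlorophyll declines
#' along a Weibull-type curve
#' \deqn{chl(t) = chl_{min} + (chl_{max} - chl_{min}) e^{-(t/\lambda)^k}}
#' of thermal time t, and SPAD readings are obtained by inverting the
#' exponential SPAD-to-chlorophyll calibration `chl = a exp(b SPAD)`.
#'
#' @param n_plots number of plots.
#' @param n_layers number of leaf layers per plot.
#' @param layer_area_fractions share of total canopy leaf area per layer
#'   (must sum to 1; top layer first).
#' @param chl_max,chl_min upper/lower chlorophyll asymptotes (g m^-2 leaf
#'   area).
#' @param weibull_scale decline scale lambda in degree days; per-plot and
#'   per-layer variation is applied around it (lower layers senesce
#'   earlier).
#' @param weibull_shape decline shape k (> 0, unitless).
#' @param spad_calibration named vector `c(a=, b=)` of the exponential
#'   SPAD calibration; `b` must be nonzero so that it is invertible.
#' @param thermal_time_grid degree-day measurement grid (since sowing).
#' @param noise_sd additive chlorophyll noise sd (g m^-2).
#' @param seed integer seed.
#' @return object of class `senescence_sim_config`.
#' @export
senescence_sim_config <- function(n_plots = 24,
                                  n_layers = 4,
                                  layer_area_fractions = c(0.40, 0.30, 0.20, 0.10),
                                  chl_max = 0.60,
                                  chl_min = 0.05,
                                  weibull_scale = 1600,
                                  weibull_shape = 9,
                                  spad_calibration = c(a = 0.06, b = 0.04),
                                  thermal_time_grid = seq(1250, 2050, by = 50),
                                  noise_sd = 0.01,
                                  seed = 20170404) {
  cfg <- list(n_plots = n_plots, n_layers = n_layers,
              layer_area_fractions = layer_area_fractions,
              chl_max = chl_max, chl_min = chl_min,
              weibull_scale = weibull_scale, weibull_shape = weibull_shape,
              spad_calibration = spad_calibration,
              thermal_time_grid = thermal_time_grid,
              noise_sd = noise_sd, seed = seed)
  class(cfg) <- "senescence_sim_config"
  validate_senescence_config(cfg)
  cfg
}

validate_senescence_config <- function(cfg) {
  if (length(cfg$layer_area_fractions) != cfg$n_layers ||
      abs(sum(cfg$layer_area_fractions) - 1) > 1e-9) {
    stop("invalid configuration field 'layer_area_fractions': must have ",
         cfg$n_layers, " entries summing to 1", call. = FALSE)
  }
  if (!(cfg$chl_max > cfg$chl_min) || cfg$chl_min < 0) {
    stop("invalid configuration: need chl_max > chl_min >= 0", call. = FALSE)
  }
  if (cfg$weibull_shape <= 0 || cfg$weibull_scale <= 0) {
    stop("invalid configuration: Weibull scale and shape must be > 0",
         call. = FALSE)
  }
  cal <- cfg$spad_calibration
  if (!all(c("a", "b") %in% names(cal)) || cal[["a"]] <= 0 ||
      cal[["b"]] == 0) {
    stop("invalid configuration field 'spad_calibration': ",
         "need a > 0 and b != 0 (b = 0 is not invertible)", call. = FALSE)
  }
  invisible(cfg)
}

weibull_decline <- function(t, hi, lo, scale, shape) {
  lo + (hi - lo) * exp(-(t / scale)^shape)
}

#' Generate a synthetic SPAD senescence trial
#'
#' Per plot and leaf layer, chlorophyll declines along a Weibull curve of
#' thermal time (lower layers senescing earlier), noise is added, and the
#' result is converted to SPAD readings by inverting the exponential
#' calibration. The true generating parameters are attached as attribute
#' `"truth"` for parameter-recovery tests.
#'
#' @param config a [senescence_sim_config()].
#' @return data.frame with columns `plot_id`, `genotype`, `thermal_time`,
#'   `layer`, `spad`, `area_fraction`; attribute `"truth"` holds the
#'   per-plot/layer Weibull parameters.
#' @export
generate_spad_trial <- function(config = senescence_sim_config()) {
  validate_senescence_config(config)
  set.seed(config$seed + 2L)
  a <- config$spad_calibration[["a"]]
  b <- config$spad_calibration[["b"]]
  rows <- list(); truth <- list()
  for (p in seq_len(config$n_plots)) {
    pid <- sprintf("S%03d", p)
    geno <- paste0("g", ((p - 1L) %% 8L) + 1L)
    plot_scale <- config$weibull_scale * exp(rnorm(1, sd = 0.03))
    plot_shape <- config$weibull_shape * exp(rnorm(1, sd = 0.05))
    for (l in seq_len(config$n_layers)) {
      layer_scale <- plot_scale * (1 - 0.04 * (l - 1))  # lower layers earlier
      chl <- weibull_decline(config$thermal_time_grid, config$chl_max,
                             config$chl_min, layer_scale, plot_shape)
      chl_obs <- pmax(chl + rnorm(length(chl), sd = config$noise_sd), 1e-4)
      spad <- log(chl_obs / a) / b
      rows[[length(rows) + 1L]] <- data.frame(
        plot_id = pid, genotype = geno,
        thermal_time = config$thermal_time_grid, layer = l,
        spad = spad,
        area_fraction = config$layer_area_fractions[l],
        stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        plot_id = pid, layer = l, chl_max = config$chl_max,
        chl_min = config$chl_min, scale = layer_scale, shape = plot_shape,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- do.call(rbind, truth)
  out
}
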