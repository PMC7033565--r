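#' Convert SPAD readings to leaf chlorophyll concentration
#'
#' SPAD meter readings relate nonlinearly to chlorophyll; the conversion
#' used here is the exponential family chl = a exp(b SPAD) in g m^-2 of
#' leaf area. The calibration coefficients are species-specific and must
#' be supplied by the user (for wheat, published SPAD-chlorophyll
#' calibrations of this exponential form are available).
#'
#' @param spad numeric SPAD readings (unitless meter units).
#' @param calibration named numeric vector `c(a=, b=)`.
#' @return chlorophyll concentration, g m^-2 leaf area.
#' @export
spad_to_chl <- function(spad, calibration) {
  if (missing(calibration) || is.null(calibration) ||
      !all(c("a", "b") %in% names(calibration))) {
    stop("supply the SPAD calibration as c(a=, b=) for chl = a*exp(b*SPAD); ",
         "the coefficients are species-specific and not hard-coded",
         call. = FALSE)
  }
  calibration[["a"]] * exp(calibration[["b"]] * spad)
}

#' Area-weighted canopy mean chlorophyll
#'
#' Chlorophyll concentrations of each leaf layer are multiplied by that
#' layer's fraction of the overall canopy leaf area; the sum of the
#' weighted concentrations is the average canopy chlorophyll
#' concentration in g m^-2.
#'
#' @param layer_chl per-layer chlorophyll concentrations (g m^-2).
#' @param area_fractions per-layer area fractions (must sum to 1 within
#'   1e-6).
#' @return canopy mean chlorophyll (g m^-2).
#' @export
canopy_chlorophyll <- function(layer_chl, area_fractions) {
  stopifnot(length(layer_chl) == length(area_fractions))
  s <- sum(area_fractions)
  if (abs(s - 1) > 1e-6) {
    stop("layer area fractions must sum to 1; got ", format(s),
         call. = FALSE)
  }
  sum(layer_chl * area_fractions)
}

#' Fit a Weibull senescence curve and derive canopy greenness
#'
#' Fits, per plot, the declining Weibull-type curve
#' \deqn{chl(t) = lo + (hi - lo) e^{-(t/\lambda)^k}}
#' to canopy chlorophyll over thermal time by bounded
#' Levenberg-Marquardt least squares with seeded multi-start. Greenness
#' normalization follows the fitted curve: every value is reduced by the
#' minimum value of the fit (its lower asymptote) and divided by the
#' maximum of the min-reduced fit, so the normalized fitted curve is 1 at
#' its maximum and 0 at its minimum. The observed ("measured canopy
#' greenness") series is normalized with the same constants; it is
#' therefore approximately, not forcedly, inside \[0, 1\] in the presence
#' of noise.
#'
#' @param thermal_time degree days since sowing (>= 5 points spanning the
#'   decline).
#' @param chl canopy chlorophyll at those times (g m^-2).
#' @param n_starts number of multi-start attempts.
#' @param seed seed for the start jitter.
#' @return object of class `greenness_curve`: parameters `hi`, `lo`,
#'   `scale`, `shape`; `fitted` chlorophyll; `fitted_greenness` and
#'   `measured_greenness` in \[0, 1\]; `diagnostics` (residual sd,
#'   convergence, declining flag).
#' @export
fit_greenness <- function(thermal_time, chl, n_starts = 5, seed = 1) {
  stopifnot(length(thermal_time) == length(chl))
  if (length(chl) < 5) {
    stop("need at least 5 time points per plot", call. = FALSE)
  }
  if (is.unsorted(thermal_time, strictly = TRUE)) {
    stop("thermal_time must be strictly increasing within a plot",
         call. = FALSE)
  }
  hi0 <- max(chl); lo0 <- max(min(chl), 1e-6)
  half <- lo0 + (hi0 - lo0) / 2
  below <- which(chl <= half)
  scale0 <- if (length(below)) thermal_time[below[1]] else
    max(thermal_time)
  starts <- withr::with_seed(seed, lapply(seq_len(n_starts), function(i) {
    list(hi = hi0 * runif(1, 0.9, 1.1),
         lo = lo0 * runif(1, 0.5, 1.5),
         scale = scale0 * runif(1, 0.8, 1.2),
         shape = c(2, 5, 8, 12, 20)[((i - 1) %% 5) + 1] * runif(1, 0.8, 1.2))
  }))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(chl ~ lo + (hi - lo) * exp(-(thermal_time / scale)^shape),
                        start = st,
                        lower = c(hi = 1e-8, lo = 0, scale = 1e-3, shape = 1e-3),
                        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    stop("Weibull greenness fit did not converge in ", n_starts,
         " starts (best residual: none)", call. = FALSE)
  }
  p <- as.list(coef(best$fit))
  # normalization constants from the fitted curve's extremes as a function:
  # its maximum (hi, at thermal time 0) and minimum (lo, the asymptote)
  min_fit <- min(p$hi, p$lo)
  denom <- abs(p$hi - p$lo)
  if (denom < 1e-10) {
    stop("degenerate Weibull fit: flat curve (hi == lo)", call. = FALSE)
  }
  fitted_chl <- weibull_decline(thermal_time, p$hi, p$lo, p$scale, p$shape)
  structure(list(
    parameters = list(hi = p$hi, lo = p$lo, scale = p$scale, shape = p$shape),
    thermal_time = thermal_time,
    chl = chl,
    fitted = fitted_chl,
    min_fit = min_fit,
    denom = denom,
    fitted_greenness = (fitted_chl - min_fit) / denom,
    measured_greenness = (chl - min_fit) / denom,
    diagnostics = list(
      residual_sd = sqrt(best$rss / max(length(chl) - 4, 1)),
      convergence = TRUE,
      declining = p$hi > p$lo)),
    class = "greenness_curve")
}

#' Evaluate the normalized fitted greenness curve at arbitrary thermal times
#'
#' @param curve a [fit_greenness()] object.
#' @param thermal_time degree days at which to evaluate.
#' @return normalized greenness values; 1 at the curve's maximum (thermal
#'   time 0), 0 at its asymptotic minimum.
#' @export
greenness_at <- function(curve, thermal_time) {
  stopifnot(inherits(curve, "greenness_curve"))
  p <- curve$parameters
  (weibull_decline(thermal_time, p$hi, p$lo, p$scale, p$shape) -
     curve$min_fit) / curve$denom
}

#' Fit greenness curves for a whole SPAD trial
#'
#' Runs the full chain per plot: SPAD to chlorophyll via the calibration,
#' area-weighted canopy aggregation over the leaf layers, Weibull fit and
#' greenness normalization.
#'
#' @param spad_data data.frame with columns `plot_id`, `thermal_time`,
#'   `layer`, `spad`, `area_fraction` (see [generate_spad_trial()]).
#' @param calibration SPAD calibration `c(a=, b=)`.
#' @param ... passed to [fit_greenness()].
#' @return named list of [fit_greenness()] curves, one per plot.
#' @export
fit_greenness_trial <- function(spad_data, calibration, ...) {
  need <- c("plot_id", "thermal_time", "layer", "spad", "area_fraction")
  miss <- setdiff(need, names(spad_data))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  spad_data$chl <- spad_to_chl(spad_data$spad, calibration)
  out <- lapply(split(spad_data, spad_data$plot_id), function(d) {
    tt <- sort(unique(d$thermal_time))
    canopy <- vapply(tt, function(t) {
      dt <- d[d$thermal_time == t, ]
      dt <- dt[order(dt$layer), ]
      canopy_chlorophyll(dt$chl, dt$area_fraction)
    }, 1.0)
    fit_greenness(tt, canopy, ...)
  })
  out
}

#' Predicted canopy greenness from a GAI prediction series
#'
#' After the onset of senescence, predicted GAI values are divided by the
#' prediction at the onset date, giving a unitless predicted greenness
#' that is 1 at onset by construction and comparable to the measured
#' (chlorophyll-based) canopy greenness.
#'
#' @param dates dates (or thermal times) of the predictions.
#' @param gai_pred predicted GAI values.
#' @param onset_date senescence onset; a prediction must exist there and
#'   be > 0.
#' @return data.frame (`date`, `greenness`) for dates >= onset.
#' @export
predicted_greenness <- function(dates, gai_pred, onset_date) {
  stopifnot(length(dates) == length(gai_pred))
  i0 <- which(dates == onset_date)
  if (length(i0) != 1) {
    stop("no (unique) prediction at the onset date", call. = FALSE)
  }
  g0 <- gai_pred[i0]
  if (!is.finite(g0) || g0 <= 0) {
    stop("predicted GAI at onset must be > 0; got ", format(g0),
         call. = FALSE)
  }
  keep <- dates >= onset_date
  data.frame(date = dates[keep], greenness = gai_pred[keep] / g0)
}

#' Agreement between measured and predicted canopy greenness
#'
#' Aligns the two series on their common dates and reports MAE and the
#' squared Pearson correlation. The onset date itself is excluded by
#' default: both series equal 1 there by construction, a self-explanatory
#' perfect fit that would flatter the statistics.
#'
#' @param measured,predicted data.frames with columns `date` and
#'   `greenness`.
#' @param exclude_onset drop the onset date (default TRUE).
#' @param onset_date the onset date; defaults to the earliest common date.
#' @return list with `mae`, `r2` and `n` (dates used).
#' @export
greenness_agreement <- function(measured, predicted, exclude_onset = TRUE,
                                onset_date = NULL) {
  m <- merge(measured, predicted, by = "date",
             suffixes = c("_meas", "_pred"))
  if (exclude_onset) {
    if (is.null(onset_date)) onset_date <- min(m$date)
    m <- m[m$date != onset_date, , drop = FALSE]
  }
  if (nrow(m) < 2) {
    stop("need at least 2 common dates", call. = FALSE)
  }
  r <- m$greenness_pred - m$greenness_meas
  list(mae = mean(abs(r)),
       r2 = cor(m$greenness_meas, m$greenness_pred)^2,
       n = nrow(m))
}
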