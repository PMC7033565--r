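#' Interpolate a per-plot GAI series to a daily grid
#'
#' GAI between flight dates is linearly interpolated on a daily calendar
#' grid covering the series span (no extrapolation). Endpoint days
#' reproduce the flight-date values exactly.
#'
#' @param dates Date vector of flight dates (distinct, any order).
#' @param gai predicted GAI at those dates.
#' @return data.frame with columns `date` (daily) and `gai`.
#' @export
interpolate_daily <- function(dates, gai) {
  stopifnot(length(dates) == length(gai))
  dates <- as.Date(dates)
  if (anyDuplicated(dates)) stop("duplicate dates", call. = FALSE)
  if (length(dates) < 2) stop("need at least 2 dates", call. = FALSE)
  o <- order(dates)
  dates <- dates[o]; gai <- gai[o]
  grid <- seq(min(dates), max(dates), by = "day")
  data.frame(date = grid,
             gai = approx(as.numeric(dates), gai, xout = as.numeric(grid),
                          method = "linear", rule = 1)$y)
}

#' Green area duration (GAD)
#'
#' The time integral of the piecewise-linear GAI course over an
#' integration window, in m^2 m^-2 d (trapezoidal rule, which is exact
#' for a piecewise-linear integrand). GAD is additive over adjacent
#' windows and scales linearly with GAI. An optional sowing-date anchor
#' (GAI 0) can be prepended so that integration starts at sowing rather
#' than at the first flight.
#'
#' @param dates Date vector of flight dates.
#' @param gai predicted GAI at those dates.
#' @param window length-2 Date vector inside the series span; defaults to
#'   the full span.
#' @param anchor_sowing optional sowing date (before the first flight) at
#'   which GAI 0 is anchored.
#' @param clip_zero truncate negative GAI at 0 before integrating
#'   (default off; unstable models legitimately predict below zero and
#'   the diagnostics depend on it).
#' @return GAD in m^2 m^-2 d.
#' @export
green_area_duration <- function(dates, gai, window = NULL,
                                anchor_sowing = NULL, clip_zero = FALSE) {
  dates <- as.Date(dates)
  if (anyDuplicated(dates)) stop("duplicate dates", call. = FALSE)
  o <- order(dates); dates <- dates[o]; gai <- gai[o]
  if (!is.null(anchor_sowing)) {
    anchor_sowing <- as.Date(anchor_sowing)
    if (anchor_sowing >= min(dates)) {
      stop("sowing anchor must precede the first flight", call. = FALSE)
    }
    dates <- c(anchor_sowing, dates)
    gai <- c(0, gai)
  }
  if (clip_zero) gai <- pmax(gai, 0)
  if (is.null(window)) window <- range(dates)
  window <- as.Date(window)
  if (window[1] < min(dates) || window[2] > max(dates) ||
      window[1] > window[2]) {
    stop("integration window outside the series span", call. = FALSE)
  }
  if (window[1] == window[2]) return(0)
  t <- as.numeric(dates)
  knots <- sort(unique(c(as.numeric(window),
                         t[t >= as.numeric(window[1]) &
                             t <= as.numeric(window[2])])))
  vals <- approx(t, gai, xout = knots, method = "linear")$y
  pracma::trapz(knots, vals)
}

#' Progressive explained variance of final biomass by green area duration
#'
#' For each date x of the evaluation grid, the green area duration from
#' the season start to x is computed per plot and its squared Pearson
#' correlation with final biomass across plots is reported. The final-date
#' value is the whole-season GAD-biomass R^2. The curve need not be
#' monotone: a model that is unstable late in the season can lose
#' explanatory power as more data accrue.
#'
#' @param series data.frame with columns `plot_id`, `date`, `gai_pred`.
#' @param biomass data.frame with columns `plot_id`, `biomass`.
#' @param eval_dates dates at which to evaluate; defaults to all flight
#'   dates after the first.
#' @param anchor_sowing,clip_zero passed to [green_area_duration()].
#' @return data.frame with columns `date` and `r2`.
#' @export
progressive_r2 <- function(series, biomass, eval_dates = NULL,
                           anchor_sowing = NULL, clip_zero = FALSE) {
  stopifnot(all(c("plot_id", "date", "gai_pred") %in% names(series)),
            all(c("plot_id", "biomass") %in% names(biomass)))
  series$date <- as.Date(series$date)
  plots <- intersect(unique(series$plot_id), biomass$plot_id)
  if (length(plots) < 3) {
    stop("need at least 3 plots with biomass; got ", length(plots),
         call. = FALSE)
  }
  start <- min(series$date)
  if (is.null(eval_dates)) {
    eval_dates <- sort(unique(series$date))
    eval_dates <- eval_dates[eval_dates > start]
  }
  b <- biomass$biomass[match(plots, biomass$plot_id)]
  per_plot <- split(series, series$plot_id)
  r2 <- vapply(as.list(eval_dates), function(x) {
    gad <- vapply(plots, function(p) {
      d <- per_plot[[p]]
      win_start <- if (is.null(anchor_sowing)) min(d$date) else
        as.Date(anchor_sowing)
      green_area_duration(d$date, d$gai_pred,
                          window = c(win_start, as.Date(x)),
                          anchor_sowing = anchor_sowing,
                          clip_zero = clip_zero)
    }, 1.0)
    if (sd(gad) == 0 || sd(b) == 0) return(NA_real_)
    cor(gad, b)^2
  }, 1.0)
  data.frame(date = as.Date(eval_dates), r2 = r2)
}

#' Whole-season GAI prediction for a reflectance series
#'
#' Convenience wrapper: computes predictors, applies a GAI model per plot
#' and date, and returns a tidy season series ready for
#' [green_area_duration()] and [progressive_r2()].
#'
#' @param reflectance data.frame of reflectance records (`plot_id`,
#'   `date`, bands).
#' @param model a [gai_model].
#' @param model_name label stored in the output.
#' @param clip_at_zero passed to [predict_gai()].
#' @return data.frame `plot_id`, `date`, `model`, `gai_pred`.
#' @export
predict_season <- function(reflectance, model,
                           model_name = model$provenance$name %||% model$family,
                           clip_at_zero = FALSE) {
  pred <- compute_predictors(reflectance)
  ok <- pred$valid
  out <- data.frame(plot_id = reflectance$plot_id,
                    date = as.Date(reflectance$date),
                    model = model_name,
                    gai_pred = NA_real_,
                    stringsAsFactors = FALSE)
  out$gai_pred[ok] <- predict_gai(model, pred[ok, , drop = FALSE],
                                  clip_at_zero = clip_at_zero)
  out
}
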