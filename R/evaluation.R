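#' Mean absolute and root mean square prediction error
#'
#' MAE weighs all residuals equally and is the primary comparison metric
#' here (predictive power at low GAI matters as much as at high GAI);
#' RMSE is reported alongside for comparability with other studies.
#'
#' @param predicted,observed equal-length finite numeric vectors.
#' @return list with elements `mae` and `rmse` (m^2 m^-2).
#' @export
error_metrics <- function(predicted, observed) {
  if (length(predicted) == 0 || length(observed) == 0) {
    stop("empty input", call. = FALSE)
  }
  if (length(predicted) != length(observed)) {
    stop("predicted and observed differ in length", call. = FALSE)
  }
  if (any(!is.finite(predicted)) || any(!is.finite(observed))) {
    stop("non-finite values in input", call. = FALSE)
  }
  r <- predicted - observed
  list(mae = mean(abs(r)), rmse = sqrt(mean(r^2)))
}

#' GAI class scheme
#'
#' The default seven-class scheme used to resolve model sensitivity across
#' the season: an exact-zero "DeadPlant" class (ripe or bare-soil records
#' are assigned GAI 0), then (0, 0.25), \[0.25, 2), \[2, 3), \[3, 4),
#' \[4, 5) and \[5, Inf). Interval boundaries belong to the left-closed
#' upper class for determinism. The classes partition \[0, Inf).
#'
#' @param breaks increasing numeric vector of interior class edges
#'   (excluding the exact-zero class), starting at 0 and ending at `Inf`.
#' @param labels optional class labels; defaults are derived from the
#'   breaks.
#' @return object of class `gai_class_scheme`.
#' @export
gai_class_scheme <- function(breaks = c(0, 0.25, 2, 3, 4, 5, Inf),
                             labels = NULL) {
  stopifnot(length(breaks) >= 2, !is.unsorted(breaks, strictly = TRUE),
            breaks[1] == 0, is.infinite(breaks[length(breaks)]))
  if (is.null(labels)) {
    lo <- breaks[-length(breaks)]; hi <- breaks[-1]
    labels <- ifelse(is.infinite(hi), paste0(">=", lo),
                     paste0("[", lo, ",", hi, ")"))
    labels[1] <- paste0("(0,", hi[1], ")")
  }
  structure(list(breaks = breaks, labels = c("DeadPlant", labels)),
            class = "gai_class_scheme")
}

#' Classify observations into GAI classes
#'
#' @param gai numeric vector of (observed) GAI values, >= 0.
#' @param scheme a [gai_class_scheme()].
#' @return factor with the scheme's class labels.
#' @export
classify_gai <- function(gai, scheme = gai_class_scheme()) {
  stopifnot(inherits(scheme, "gai_class_scheme"), all(gai >= 0))
  idx <- findInterval(gai, scheme$breaks, left.open = FALSE) + 1L
  idx[gai == 0] <- 1L
  factor(scheme$labels[idx], levels = scheme$labels)
}

#' Per-class error breakdown
#'
#' Splits the prediction errors by the class of the OBSERVED (reference)
#' GAI and reports per class the sample size, MAE, RMSE and relative MAE
#' (rMAE = MAE / mean observed GAI of the class). The rMAE of the
#' exact-zero "DeadPlant" class is NA: division by a class mean of 0 is
#' not possible. Empty classes are reported with n = 0 and NA metrics.
#'
#' @param predicted,observed equal-length numeric vectors; classification
#'   uses `observed`.
#' @param scheme a [gai_class_scheme()].
#' @return data.frame with columns `class`, `n`, `mae`, `rmse`, `rmae`.
#' @export
class_breakdown <- function(predicted, observed, scheme = gai_class_scheme()) {
  stopifnot(length(predicted) == length(observed))
  cls <- classify_gai(observed, scheme)
  out <- lapply(levels(cls), function(lv) {
    i <- cls == lv
    if (!any(i)) {
      return(data.frame(class = lv, n = 0L, mae = NA_real_,
                        rmse = NA_real_, rmae = NA_real_))
    }
    m <- error_metrics(predicted[i], observed[i])
    mu <- mean(observed[i])
    data.frame(class = lv, n = sum(i), mae = m$mae, rmse = m$rmse,
               rmae = if (mu == 0) NA_real_ else m$mae / mu)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Relative increase of predictive error from calibration to evaluation
#'
#' @param mae_calibration,mae_evaluation MAE on the calibration and on the
#'   independent evaluation set (calibration MAE must be > 0).
#' @return percent increase, 100 (MAE_eval - MAE_cal) / MAE_cal.
#' @export
error_increase <- function(mae_calibration, mae_evaluation) {
  if (!is.finite(mae_calibration) || mae_calibration <= 0) {
    stop("mae_calibration must be > 0", call. = FALSE)
  }
  100 * (mae_evaluation - mae_calibration) / mae_calibration
}

#' Remove implausibly high GAI reference values
#'
#' Reference GAI values strictly above the threshold (default 7 m^2 m^-2,
#' values that do not occur as treatment means under the emulated growing
#' conditions) are excluded; the boundary value itself is kept. The
#' removed rows are logged in the `"exclusion_log"` attribute, so the
#' filter is idempotent and auditable.
#'
#' @param data data.frame with a GAI column.
#' @param max_gai exclusion threshold (strictly-above rule).
#' @param gai_col name of the GAI column.
#' @return the filtered data.frame; attribute `"exclusion_log"` holds the
#'   excluded rows.
#' @export
apply_cleaning_filters <- function(data, max_gai = 7, gai_col = "gai") {
  if (!gai_col %in% names(data)) {
    stop("GAI column '", gai_col, "' not found", call. = FALSE)
  }
  drop <- data[[gai_col]] > max_gai
  out <- data[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusion_log") <- data[drop, , drop = FALSE]
  if (any(drop)) {
    message("apply_cleaning_filters: excluded ", sum(drop), " record(s) with ",
            gai_col, " > ", max_gai)
  }
  out
}

#' Compare a cultivar-blind and a cultivar-extended GAI model
#'
#' Fits, on the calibration split, a "common" linear model (GAI from the
#' reflectance predictors only) and an "extended" model adding the
#' cultivar as a factor interacting with the predictors, then reports the
#' MAE of both models on the calibration and evaluation splits and the
#' nested-model ANOVA F-test p-value for the cultivar effect.
#'
#' @param data data.frame with predictor columns, the response, a
#'   `cultivar` column and a `role` column (`"calibration"` /
#'   `"evaluation"`).
#' @param predictor_spec predictor column names.
#' @param response response column name.
#' @return list with `mae_common_cal`, `mae_common_eval`,
#'   `mae_extended_cal`, `mae_extended_eval`, the corresponding RMSEs
#'   (`rmse_*`; on the calibration split the extended RMSE can never
#'   exceed the common one, a least-squares nesting guarantee that does
#'   not carry over to the MAE), and `anova_p`.
#' @export
cultivar_model_comparison <- function(data,
                                      predictor_spec = c("nir_re"),
                                      response = "gai") {
  stopifnot(all(c("cultivar", "role", response, predictor_spec) %in% names(data)))
  if (length(unique(data$cultivar)) < 2) {
    stop("need at least 2 cultivars", call. = FALSE)
  }
  data$cultivar <- factor(data$cultivar)
  cal <- data[data$role == "calibration", , drop = FALSE]
  ev <- data[data$role == "evaluation", , drop = FALSE]
  if (nrow(cal) == 0) stop("no calibration rows", call. = FALSE)
  rhs <- paste(predictor_spec, collapse = " + ")
  f_common <- as.formula(paste(response, "~", rhs))
  f_ext <- as.formula(paste(response, "~ (", rhs, ") * cultivar"))
  m_common <- lm(f_common, data = cal)
  m_ext <- lm(f_ext, data = cal)
  an <- anova(m_common, m_ext)
  err <- function(m, d, fun) {
    if (nrow(d) == 0) return(NA_real_)
    fun(predict(m, newdata = d) - d[[response]])
  }
  mae_f <- function(r) mean(abs(r)); rmse_f <- function(r) sqrt(mean(r^2))
  list(mae_common_cal = err(m_common, cal, mae_f),
       mae_common_eval = err(m_common, ev, mae_f),
       mae_extended_cal = err(m_ext, cal, mae_f),
       mae_extended_eval = err(m_ext, ev, mae_f),
       rmse_common_cal = err(m_common, cal, rmse_f),
       rmse_common_eval = err(m_common, ev, rmse_f),
       rmse_extended_cal = err(m_ext, cal, rmse_f),
       rmse_extended_eval = err(m_ext, ev, rmse_f),
       anova_p = an[["Pr(>F)"]][2])
}
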