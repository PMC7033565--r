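#' @title GAI model objects
#' @description
#' A `gai_model` bundles a model family, its ordered predictor names, any
#' preprocessing (centering/scaling statistics estimated on the training
#' data only), the fitted parameters or learner state, and provenance
#' (registry vs refit, sample size, CV table). Prediction is deterministic
#' given a fitted model.
#' @name gai_model
NULL

new_gai_model <- function(family, predictor_spec, parameters = NULL,
                          fit = NULL, preprocessing = NULL,
                          provenance = list(source = "refit")) {
  structure(list(family = family, predictor_spec = predictor_spec,
                 parameters = parameters, fit = fit,
                 preprocessing = preprocessing, provenance = provenance),
            class = "gai_model")
}

#' @export
print.gai_model <- function(x, ...) {
  cat("<gai_model>", x$family, "\n  predictors:",
      paste(x$predictor_spec, collapse = ", "),
      "\n  source:", x$provenance$source %||% "refit", "\n")
  if (!is.null(x$parameters$coef)) {
    print(round(x$parameters$coef, 6))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.linear_families <- c("single_band_linear", "ratio_linear",
                      "ratio_linear_interaction")
.advanced_families <- c("pls", "svm_linear", "svm_radial", "knn", "mars",
                        "boosted_trees")

# Evaluate a named linear-coefficient vector on a predictor table.
# Interaction terms are encoded as "a*b" products of predictor names.
.eval_linear_terms <- function(coefs, data) {
  out <- rep(0, nrow(data))
  for (term in names(coefs)) {
    if (term == "(Intercept)") {
      out <- out + coefs[[term]]
    } else {
      vars <- strsplit(term, "*", fixed = TRUE)[[1]]
      col <- Reduce(`*`, lapply(vars, function(v) data[[v]]))
      out <- out + coefs[[term]] * col
    }
  }
  out
}

#' The calibrated GAI model registry
#'
#' Loads the read-only registry of calibrated vegetation-index GAI models
#' shipped with the package: the three NIR simple-ratio linear models
#' (`NIR_RE`, `NIR_Red`, `NIR_Green`), the four-band `VIQUO` model (a
#' linear combination of NIR/RE, NIR/Red and NIR/Green), its full
#' interaction variant `VIQUO_interaction`, and the exponential NDVI model
#' `NDVI_exp` (GAI = a exp(b NDVI)). Coefficients are stored to all
#' published digits in a JSON data file.
#'
#' @param name optional model name; omit to get the full named list.
#' @return a `gai_model` (if `name` given) or named list of them.
#' @export
#' @examples
#' predict_gai(gai_registry("VIQUO"),
#'             data.frame(nir_re = 0, nir_red = 0, nir_green = 0))
gai_registry <- function(name = NULL) {
  path <- system.file("extdata", "gai_model_registry.json",
                      package = "gaiseason", mustWork = TRUE)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  models <- lapply(names(raw), function(nm) {
    entry <- raw[[nm]]
    if (identical(entry$family, "ndvi_exponential")) {
      params <- list(a = entry$a, b = entry$b)
    } else {
      params <- list(coef = unlist(entry$coef))
    }
    new_gai_model(entry$family, unlist(entry$predictors), parameters = params,
                  provenance = list(source = "registry", name = nm))
  })
  names(models) <- names(raw)
  if (is.null(name)) return(models)
  if (!name %in% names(models)) {
    stop("unknown registry model '", name, "'; available: ",
         paste(names(models), collapse = ", "), call. = FALSE)
  }
  models[[name]]
}

#' Predict GAI from a fitted or registry model
#'
#' Evaluates a [gai_model] on a table of predictors (as produced by
#' [compute_predictors()]). Negative predictions are returned as-is: some
#' simple-ratio models legitimately predict below zero at sparse cover,
#' and downstream diagnostics depend on the unclipped values. Set
#' `clip_at_zero = TRUE` to truncate at 0 as an explicit post-processing
#' step.
#'
#' @param model a `gai_model`.
#' @param predictors data.frame containing every column named in
#'   `model$predictor_spec`.
#' @param clip_at_zero truncate negative predictions at 0 (default off).
#' @return numeric vector of GAI predictions (m^2 m^-2).
#' @export
predict_gai <- function(model, predictors, clip_at_zero = FALSE) {
  stopifnot(inherits(model, "gai_model"))
  need <- model$predictor_spec
  miss <- setdiff(need, names(predictors))
  if (length(miss)) {
    stop("missing predictor(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- if (model$family %in% .linear_families) {
    .eval_linear_terms(model$parameters$coef, predictors)
  } else if (model$family == "ndvi_exponential") {
    model$parameters$a * exp(model$parameters$b * predictors$ndvi)
  } else if (model$family %in% .advanced_families) {
    X <- as.matrix(predictors[, need, drop = FALSE])
    X <- .apply_preprocessing(X, model$preprocessing)
    .predict_learner(model$family, model$fit, X)
  } else {
    stop("unknown model family: ", model$family, call. = FALSE)
  }
  if (clip_at_zero) out <- pmax(out, 0)
  as.numeric(out)
}

#' @export
predict.gai_model <- function(object, newdata, ...) {
  predict_gai(object, newdata, ...)
}

#' Fit a vegetation-index GAI model by least squares
#'
#' Linear families are fitted by ordinary least squares: additive terms for
#' `single_band_linear`/`ratio_linear`, the full factorial interaction
#' expansion (all products of the predictors, 8 terms for 3 predictors)
#' for `ratio_linear_interaction`. The `ndvi_exponential` family fits
#' GAI = a exp(b NDVI) by Levenberg-Marquardt nonlinear least squares,
#' initialized from a log-linear regression of log(GAI + 1e-3) on NDVI.
#'
#' @param data data.frame holding the predictor columns and the response.
#' @param family one of `single_band_linear`, `ratio_linear`,
#'   `ratio_linear_interaction`, `ndvi_exponential`.
#' @param predictor_spec character vector of predictor column names
#'   (`"ndvi"` for the exponential family).
#' @param response name of the GAI column.
#' @return a fitted [gai_model].
#' @export
fit_vi_model <- function(data, family = "ratio_linear",
                         predictor_spec = c("nir_re", "nir_red", "nir_green"),
                         response = "gai") {
  stopifnot(response %in% names(data))
  miss <- setdiff(predictor_spec, names(data))
  if (length(miss)) {
    stop("missing predictor column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- data[, c(response, predictor_spec)]
  if (!all(complete.cases(df)) || !all(vapply(df, is.numeric, TRUE))) {
    stop("predictors and response must be finite numerics", call. = FALSE)
  }
  if (nrow(df) < length(predictor_spec) + 2) {
    stop("need at least p + 2 records to fit", call. = FALSE)
  }

  if (family %in% .linear_families) {
    joiner <- if (family == "ratio_linear_interaction") " * " else " + "
    fml <- as.formula(paste(response, "~",
                            paste(predictor_spec, collapse = joiner)))
    fit <- lm(fml, data = df)
    cf <- coef(fit)
    if (any(is.na(cf))) {
      stop("rank-deficient design; collinear term(s): ",
           paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
    }
    names(cf) <- gsub(":", "*", names(cf), fixed = TRUE)
    return(new_gai_model(family, predictor_spec,
                         parameters = list(coef = cf),
                         provenance = list(source = "refit", n = nrow(df),
                                           dataset_hash = rlang::hash(df),
                                           sigma = stats::sigma(fit))))
  }

  if (family == "ndvi_exponential") {
    x <- df[[predictor_spec[1]]]
    y <- df[[response]]
    init <- lm(log(pmax(y, 0) + 1e-3) ~ x)
    start <- list(a = exp(coef(init)[[1]]), b = coef(init)[[2]])
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * exp(b * x), start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) {
        stop("exponential NDVI fit did not converge (start a=",
             signif(start$a, 4), ", b=", signif(start$b, 4), "): ",
             conditionMessage(e), call. = FALSE)
      })
    cf <- coef(fit)
    return(new_gai_model("ndvi_exponential", predictor_spec,
                         parameters = list(a = cf[["a"]], b = cf[["b"]]),
                         provenance = list(source = "refit", n = nrow(df),
                                           dataset_hash = rlang::hash(df))))
  }
  stop("unknown family '", family, "' for fit_vi_model; advanced learners ",
       "are fitted with fit_advanced_model()", call. = FALSE)
}

#' Assign dates to cross-validation folds
#'
#' Grouped cross-validation in which the hold-out sample is selected by
#' date: every record of a date lands in exactly one fold, so a flight/
#' sampling campaign is never split between training and hold-out. Dates
#' are shuffled with the given seed and dealt round-robin to `k` folds.
#'
#' @param dates vector of dates (one per record, or the distinct dates).
#' @param k number of folds.
#' @param seed integer seed for the shuffle.
#' @return object of class `fold_assignment`: list with `k` and `fold`, a
#'   named integer vector mapping date (as character) to fold index.
#' @export
date_grouped_folds <- function(dates, k = 10, seed = 1) {
  u <- sort(unique(as.character(dates)))
  if (length(u) < k) {
    stop("fewer distinct dates (", length(u), ") than folds (", k, ")",
         call. = FALSE)
  }
  shuffled <- withr::with_seed(seed, sample(u))
  fold <- setNames(integer(length(u)), u)
  fold[shuffled] <- rep_len(seq_len(k), length(u))
  structure(list(k = k, fold = fold), class = "fold_assignment")
}

fold_of <- function(folds, dates) {
  stopifnot(inherits(folds, "fold_assignment"))
  f <- folds$fold[as.character(dates)]
  if (any(is.na(f))) {
    stop("date(s) without fold assignment: ",
         paste(unique(as.character(dates)[is.na(f)]), collapse = ", "),
         call. = FALSE)
  }
  unname(f)
}

.apply_preprocessing <- function(X, prep) {
  if (is.null(prep)) return(X)
  sweep(sweep(X, 2, prep$center, "-"), 2, prep$scale, "/")
}

.make_preprocessing <- function(X) {
  s <- apply(X, 2, sd)
  s[s == 0] <- 1
  list(center = colMeans(X), scale = s)
}

#' Default tuning grids for the advanced learners
#'
#' Conventional small grids: SVM cost over powers of two (plus an RBF
#' bandwidth for the radial kernel), KNN neighborhood sizes 3-9, 1-4 PLS
#' components, MARS degree 1-2, and boosted trees over depth x number of
#' trees with the minimum node size held at 10. All grids can be
#' overridden via the `tuning_grid` argument of [fit_advanced_model()].
#'
#' @param family one of the advanced learner families.
#' @return data.frame, one row per grid point.
#' @export
default_tuning_grid <- function(family) {
  switch(family,
    pls = data.frame(ncomp = 1:4),
    svm_linear = data.frame(cost = c(0.25, 0.5, 1, 2, 4)),
    svm_radial = expand.grid(cost = c(0.25, 0.5, 1, 2, 4),
                             sigma = c(0.1, 0.5, 1)),
    knn = data.frame(k = c(3, 5, 7, 9)),
    mars = data.frame(degree = c(1, 2)),
    boosted_trees = expand.grid(depth = 1:3,
                                trees = c(50, 100, 200, 300, 400, 500)),
    stop("unknown advanced family: ", family, call. = FALSE))
}

.needs_scaling <- function(family) family %in% c("pls", "svm_linear",
                                                 "svm_radial", "knn")

.fit_learner <- function(family, X, y, params, seed) {
  set.seed(seed)
  switch(family,
    pls = mixOmics::pls(X, y, ncomp = params$ncomp, scale = FALSE,
                        mode = "regression"),
    svm_linear = kernlab::ksvm(X, y, type = "eps-svr",
                               kernel = "vanilladot", C = params$cost,
                               scaled = FALSE),
    svm_radial = kernlab::ksvm(X, y, type = "eps-svr", kernel = "rbfdot",
                               kpar = list(sigma = params$sigma),
                               C = params$cost, scaled = FALSE),
    knn = caret::knnreg(X, y, k = params$k),
    mars = fit_mars(X, y, degree = params$degree),
    boosted_trees = {
      if (nrow(X) < 10) {
        stop("boosted trees require at least 10 records with the minimum ",
             "node size fixed at 10; got ", nrow(X), call. = FALSE)
      }
      xgboost::xgboost(x = X, y = y, nrounds = params$trees,
                       max_depth = params$depth, learning_rate = 0.1,
                       min_child_weight = 10, nthread = 1, verbosity = 0)
    },
    stop("unknown advanced family: ", family, call. = FALSE))
}

.predict_learner <- function(family, fit, X) {
  switch(family,
    pls = {
      nc <- fit$ncomp
      as.numeric(predict(fit, X)$predict[, 1, nc])
    },
    svm_linear = as.numeric(kernlab::predict(fit, X)),
    svm_radial = as.numeric(kernlab::predict(fit, X)),
    knn = as.numeric(predict(fit, X)),
    mars = predict_mars(fit, X),
    boosted_trees = as.numeric(predict(fit, X)),
    stop("unknown advanced family: ", family, call. = FALSE))
}

#' Fit an advanced learner with date-grouped cross-validated tuning
#'
#' Grid search over `tuning_grid`: for every grid point the cross-validated
#' error over the date-grouped folds is computed (pooled residuals), the
#' grid point with the smallest RMSE (or MAE, per `selection_metric`) is
#' selected — first point wins ties, in declared order — and the learner is
#' refitted on all data at the winning point. For PLS, SVM and KNN the
#' predictors are centered and scaled; the statistics are computed within
#' each training split (never from hold-out rows) and stored with the
#' final model.
#'
#' @param data data.frame with predictor columns, the response and a
#'   `date` column.
#' @param family one of `pls`, `svm_linear`, `svm_radial`, `knn`, `mars`,
#'   `boosted_trees`.
#' @param folds a [date_grouped_folds()] assignment.
#' @param tuning_grid data.frame of grid points (default
#'   [default_tuning_grid()]).
#' @param predictor_spec predictor column names.
#' @param response response column name.
#' @param seed integer seed re-applied before every stochastic fit.
#' @param selection_metric `"rmse"` (default) or `"mae"`.
#' @return a fitted [gai_model]; the CV table is stored in
#'   `$provenance$cv_table`.
#' @export
fit_advanced_model <- function(data, family, folds,
                               tuning_grid = default_tuning_grid(family),
                               predictor_spec = c("nir_re", "nir_red", "nir_green"),
                               response = "gai", seed = 1,
                               selection_metric = c("rmse", "mae")) {
  selection_metric <- match.arg(selection_metric)
  stopifnot(family %in% .advanced_families, nrow(tuning_grid) >= 1,
            "date" %in% names(data))
  X_all <- as.matrix(data[, predictor_spec, drop = FALSE])
  y_all <- data[[response]]
  f <- fold_of(folds, data$date)

  cv <- tuning_grid
  cv$rmse <- NA_real_; cv$mae <- NA_real_
  for (g in seq_len(nrow(tuning_grid))) {
    params <- as.list(tuning_grid[g, , drop = FALSE])
    resid <- numeric(0)
    for (fold in sort(unique(f))) {
      tr <- f != fold; te <- !tr
      if (!any(tr)) stop("empty training split for fold ", fold,
                         call. = FALSE)
      Xtr <- X_all[tr, , drop = FALSE]; Xte <- X_all[te, , drop = FALSE]
      prep <- if (.needs_scaling(family)) .make_preprocessing(Xtr) else NULL
      fit <- .fit_learner(family, .apply_preprocessing(Xtr, prep),
                          y_all[tr], params, seed)
      pred <- .predict_learner(family, fit, .apply_preprocessing(Xte, prep))
      resid <- c(resid, pred - y_all[te])
    }
    cv$rmse[g] <- sqrt(mean(resid^2))
    cv$mae[g] <- mean(abs(resid))
  }
  best <- which.min(cv[[selection_metric]])  # first wins ties
  params <- as.list(tuning_grid[best, , drop = FALSE])
  prep <- if (.needs_scaling(family)) .make_preprocessing(X_all) else NULL
  fit <- .fit_learner(family, .apply_preprocessing(X_all, prep), y_all,
                      params, seed)
  new_gai_model(family, predictor_spec, fit = fit, preprocessing = prep,
                parameters = params,
                provenance = list(source = "refit", n = nrow(data),
                                  seed = seed, cv_table = cv,
                                  selected = best,
                                  selection_metric = selection_metric,
                                  dataset_hash = rlang::hash(data)))
}
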