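#' Multivariate adaptive regression splines (MARS)
#'
#' A compact MARS regression: a forward pass that greedily adds reflected
#' pairs of hinge functions max(0, x - t) / max(0, t - x) — optionally
#' multiplied into an existing basis term up to the interaction `degree` —
#' followed by a backward pruning pass that drops terms by generalized
#' cross-validation (GCV). Knots are taken from the observed predictor
#' quantiles. Suited to the small, low-dimensional predictor sets used
#' here (a handful of band ratios).
#'
#' @param X numeric predictor matrix (columns named).
#' @param y numeric response.
#' @param degree maximum interaction degree (1 = additive).
#' @param max_terms maximum number of basis terms grown in the forward
#'   pass (including the intercept).
#' @param n_knots maximum number of candidate knots per predictor.
#' @param penalty GCV penalty per knot (conventional: 2 for additive
#'   models, 3 with interactions).
#' @return object of class `mars_fit`.
#' @export
fit_mars <- function(X, y, degree = 1, max_terms = 21, n_knots = 15,
                     penalty = if (degree > 1) 3 else 2) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X)
  # basis terms: list of lists of components (var, knot, sign); empty = intercept
  terms <- list(list())
  B <- matrix(1, n, 1)

  eval_term <- function(term, M) {
    out <- rep(1, nrow(M))
    for (cmp in term) {
      h <- cmp$sign * (M[, cmp$var] - cmp$knot)
      out <- out * pmax(h, 0)
    }
    out
  }
  rss_of <- function(Bm) {
    fit <- .lm.fit(Bm, y)
    sum(fit$residuals^2)
  }

  knots <- lapply(seq_len(ncol(X)), function(j) {
    unique(quantile(X[, j], probs = seq(0.05, 0.95,
                                        length.out = n_knots), names = FALSE))
  })

  best_rss <- rss_of(B)
  while (ncol(B) + 2 <= max_terms) {
    cand_best <- NULL
    for (p in seq_along(terms)) {
      parent <- terms[[p]]
      if (length(parent) >= degree) next
      used <- vapply(parent, function(cmp) cmp$var, 1L)
      for (j in setdiff(seq_len(ncol(X)), used)) {
        pb <- B[, p]
        for (t in knots[[j]]) {
          b1 <- pb * pmax(X[, j] - t, 0)
          b2 <- pb * pmax(t - X[, j], 0)
          if (sd(b1) < 1e-12 && sd(b2) < 1e-12) next
          rss <- rss_of(cbind(B, b1, b2))
          if (is.null(cand_best) || rss < cand_best$rss - 1e-12) {
            cand_best <- list(rss = rss, parent = p, var = j, knot = t)
          }
        }
      }
    }
    if (is.null(cand_best) || cand_best$rss > best_rss * (1 - 1e-4)) break
    p <- cand_best$parent
    terms[[length(terms) + 1L]] <- c(terms[[p]],
      list(list(var = cand_best$var, knot = cand_best$knot, sign = 1)))
    terms[[length(terms) + 1L]] <- c(terms[[p]],
      list(list(var = cand_best$var, knot = cand_best$knot, sign = -1)))
    B <- cbind(B,
               eval_term(terms[[length(terms) - 1L]], X),
               eval_term(terms[[length(terms)]], X))
    best_rss <- cand_best$rss
  }

  # backward pruning by GCV
  gcv <- function(rss, nterms) {
    c_eff <- nterms + penalty * (nterms - 1) / 2
    rss / n / (1 - c_eff / n)^2
  }
  keep <- seq_along(terms)
  best_keep <- keep
  best_gcv <- gcv(rss_of(B[, keep, drop = FALSE]), length(keep))
  while (length(keep) > 1) {
    scores <- vapply(keep[-1], function(drop_i) {
      kk <- setdiff(keep, drop_i)
      gcv(rss_of(B[, kk, drop = FALSE]), length(kk))
    }, 1.0)
    i_best <- which.min(scores)
    keep <- setdiff(keep, keep[-1][i_best])
    if (scores[i_best] < best_gcv) {
      best_gcv <- scores[i_best]
      best_keep <- keep
    }
  }
  terms <- terms[best_keep]
  Bk <- B[, best_keep, drop = FALSE]
  cf <- .lm.fit(Bk, y)$coefficients
  structure(list(terms = terms, coefficients = cf,
                 var_names = colnames(X), gcv = best_gcv,
                 eval_term = NULL),
            class = "mars_fit")
}

#' Predict from a fitted MARS model
#'
#' @param fit a [fit_mars()] object.
#' @param X predictor matrix with the training columns.
#' @return numeric predictions.
#' @export
predict_mars <- function(fit, X) {
  X <- as.matrix(X)
  B <- vapply(fit$terms, function(term) {
    out <- rep(1, nrow(X))
    for (cmp in term) {
      out <- out * pmax(cmp$sign * (X[, cmp$var] - cmp$knot), 0)
    }
    out
  }, numeric(nrow(X)))
  if (is.null(dim(B))) B <- matrix(B, nrow = 1)
  as.numeric(B %*% fit$coefficients)
}
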