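#' Binary logistic regression fit
#'
#' Maximum-likelihood logistic fit with an intercept via [stats::glm()].
#' Predictors are standardised internally for numeric stability (this leaves
#' fitted probabilities, likelihood and discrimination unchanged; reported
#' coefficients are mapped back to the original scale). Complete or
#' quasi-complete separation is detected (fitted probabilities numerically at
#' 0/1) and flagged rather than silently diverging.
#'
#' @param X Numeric matrix/data frame of predictors (may have 0 columns).
#' @param y Binary outcome (0/1, logical, or 2-level factor).
#' @return List with `coefficients`, `loglik`, `fitted`, `converged`,
#'   `separation` and the underlying `glm` object.
#' @export
fit_logistic <- function(X, y) {
  y <- as_binary(y)
  if (length(unique(y)) < 2) stop("both classes must be present")
  X <- as.matrix(X)
  if (ncol(X) > 0 && is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  ctr <- if (ncol(X)) colMeans(X) else numeric(0)
  scl <- if (ncol(X)) apply(X, 2, sd) else numeric(0)
  scl[scl == 0] <- 1
  Xs <- if (ncol(X)) sweep(sweep(X, 2, ctr), 2, scl, "/") else X
  dat <- data.frame(.y = y, Xs, check.names = FALSE)
  form <- if (ncol(X)) stats::as.formula(paste(".y ~", paste(sprintf("`%s`", colnames(X)), collapse = "+")))
    else stats::as.formula(".y ~ 1")
  fit <- suppressWarnings(glm(form, family = binomial(), data = dat))
  mu <- fit$fitted.values
  separation <- any(mu > 1 - 1e-8 | mu < 1e-8)
  beta_s <- coef(fit)
  beta_s[is.na(beta_s)] <- 0  # aliased / constant predictors carry no effect
  beta <- beta_s
  if (ncol(X)) {
    beta[-1] <- beta_s[-1] / scl
    beta[1] <- beta_s[1] - sum(beta_s[-1] * ctr / scl)
  }
  list(coefficients = beta, loglik = as.numeric(stats::logLik(fit)),
       fitted = unname(mu), converged = fit$converged,
       separation = separation, glm = fit)
}

as_binary <- function(y) {
  if (is.factor(y)) return(as.numeric(y) - 1)
  if (is.logical(y)) return(as.numeric(y))
  if (!all(y %in% c(0, 1))) stop("y must be binary (0/1, logical, or 2-level factor)")
  as.numeric(y)
}

#' Likelihood-ratio test between nested logistic fits
#'
#' @param full,reduced Fits from [fit_logistic()]; `reduced` nested in `full`.
#' @param df Degrees of freedom of the comparison (default: difference in
#'   coefficient count).
#' @return List with `statistic`, `df` and `p`.
#' @export
lr_test <- function(full, reduced, df = NULL) {
  stat <- 2 * (full$loglik - reduced$loglik)
  if (is.null(df)) df <- length(full$coefficients) - length(reduced$coefficients)
  list(statistic = stat, df = df, p = pchisq(max(stat, 0), df, lower.tail = FALSE))
}

#' Backward elimination by likelihood ratio
#'
#' Starting from the full multivariable logistic model, iteratively removes
#' the predictor whose single-term deletion has the largest likelihood-ratio
#' p-value, as long as that p-value is at or above `alpha`; stops when every
#' remaining deletion has p below `alpha`. Ties are broken by predictor order.
#' May retain zero predictors (intercept-only model).
#'
#' @param X Predictor matrix/data frame (>= 1 column).
#' @param y Binary outcome.
#' @param alpha Retention criterion (default 0.05).
#' @return List with `model` (final [fit_logistic()]), `retained` predictor
#'   names, and `steps` (a log of the deletions).
#' @export
backward_eliminate <- function(X, y, alpha = 0.05) {
  X <- as.matrix(X)
  if (ncol(X) < 1) stop("need at least one candidate predictor")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  current <- colnames(X)
  steps <- list()
  repeat {
    fit_cur <- fit_logistic(X[, current, drop = FALSE], y)
    if (length(current) == 0) break
    pvals <- vapply(current, function(v) {
      fit_red <- fit_logistic(X[, setdiff(current, v), drop = FALSE], y)
      lr_test(fit_cur, fit_red, df = 1)$p
    }, numeric(1))
    worst <- which.max(pvals)  # first index on ties
    if (pvals[worst] < alpha) break
    steps[[length(steps) + 1]] <- list(dropped = current[worst], p = unname(pvals[worst]))
    current <- setdiff(current, current[worst])
  }
  list(model = fit_logistic(X[, current, drop = FALSE], y),
       retained = current, steps = steps)
}

#' ROC curve, AUC and Youden operating point
#'
#' AUC by the trapezoidal rule over all score thresholds; the operating point
#' maximises Youden's J = sensitivity + specificity - 1 (ties broken toward
#' higher sensitivity). Computed in-sample on the supplied scores.
#'
#' @param scores Numeric predictor/score (higher = more likely positive).
#' @param y Binary outcome.
#' @return List of class `roc_summary`: `auc`, `sensitivity`, `specificity`,
#'   `threshold`, `youden_j` and the `roc` curve data frame.
#' @export
roc_summary <- function(scores, y) {
  y <- as_binary(y)
  if (length(unique(y)) < 2) stop("both classes must be present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  sens <- vapply(thr, function(t) sum(scores >= t & y == 1) / n1, numeric(1))
  spec <- vapply(thr, function(t) sum(scores < t & y == 0) / n0, numeric(1))
  fpr <- 1 - spec
  auc <- sum(diff(fpr) * (sens[-1] + sens[-length(sens)]) / 2)
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[which.max(sens[best])]
  structure(list(auc = auc, sensitivity = sens[best], specificity = spec[best],
                 threshold = thr[best], youden_j = j[best],
                 roc = data.frame(threshold = thr, sensitivity = sens,
                                  specificity = spec, fpr = fpr)),
            class = "roc_summary")
}

#' @export
print.roc_summary <- function(x, ...) {
  cat(sprintf("<roc_summary> AUC %.3f | sensitivity %.1f%% / specificity %.1f%% at threshold %.4g (Youden)\n",
              x$auc, 100 * x$sensitivity, 100 * x$specificity, x$threshold))
  invisible(x)
}

#' Univariate and multivariable diagnostic models for one group contrast
#'
#' Fits a univariate logistic model per candidate predictor, then a
#' multivariable model reduced by [backward_eliminate()], and summarises each
#' with an in-sample ROC.
#'
#' @param data Data frame containing the predictors and a `group` column.
#' @param contrast Two group labels; the second is coded 1 (the "positive").
#' @param predictors Predictor column names.
#' @param alpha Elimination criterion for the multivariable model.
#' @return List with `contrast`, `univariate` (named list of
#'   fit + roc per predictor), `multivariable` (fit, retained, roc).
#' @export
classify_contrast <- function(data, contrast, predictors, alpha = 0.05) {
  stopifnot(length(contrast) == 2L, all(predictors %in% names(data)))
  sel <- data$group %in% contrast
  d <- data[sel, , drop = FALSE]
  y <- as.numeric(d$group == contrast[2])
  X <- as.matrix(d[predictors])
  uni <- lapply(predictors, function(p) {
    fit <- fit_logistic(X[, p, drop = FALSE], y)
    list(fit = fit, roc = roc_summary(fit$fitted, y))
  })
  names(uni) <- predictors
  bw <- backward_eliminate(X, y, alpha = alpha)
  list(contrast = contrast, univariate = uni,
       multivariable = list(fit = bw$model, retained = bw$retained,
                            steps = bw$steps,
                            roc = roc_summary(bw$model$fitted, y)))
}
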