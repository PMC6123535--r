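# Leave-one-out cross-validation, error measures, comparison against the
# mean reference, and lasso-based feature selection.

#' MAE and RMSE of held-out predictions
#'
#' @param predictions,observed aligned numeric vectors.
#' @return list with `mae`, `rmse` and the absolute error vector. For any
#'   error vector `rmse >= mae` (Jensen), with equality iff all absolute
#'   errors coincide; both are 0 iff the predictions are exact.
#' @export
cv_metrics <- function(predictions, observed) {
  if (length(predictions) != length(observed)) {
    stopf("predictions and observed must be aligned")
  }
  err <- abs(predictions - observed)
  list(mae = mean(err), rmse = sqrt(mean(err^2)), abs_errors = err)
}

default_grid <- function(algorithm, X, y) {
  switch(algorithm,
    mean_ref = ,
    ols = data.frame(),
    ridge = data.frame(lambda = 10^seq(-2, 4, length.out = 13)),
    lasso = data.frame(lambda = lasso_lambda_max(X, y) *
                         10^seq(0, -3, length.out = 15)),
    tree = expand.grid(depth = c(2, 3, 4, 5), min_leaf = c(5, 10, 20)),
    # linear-kernel C is capped at 1: beyond that the linear SVR approaches
    # an unregularized linear fit while libsvm's solver slows by orders of
    # magnitude; the RBF kernel keeps the full C range
    svr = rbind(
      expand.grid(C = c(0.1, 1, 10, 100),
                  epsilon = c(0.01, 0.1) * max(stats::sd(y), 1e-12),
                  kernel = "radial", stringsAsFactors = FALSE),
      expand.grid(C = c(0.1, 1),
                  epsilon = c(0.01, 0.1) * max(stats::sd(y), 1e-12),
                  kernel = "linear", stringsAsFactors = FALSE)))
}

grid_row_hyper <- function(grid, i) {
  if (!nrow(grid)) return(list())
  as.list(grid[i, , drop = FALSE])
}

# mean squared error of `algorithm` over k inner folds, per grid row;
# ties go to the earliest (simplest) grid row
inner_cv_select <- function(algorithm, X, y, grid, folds = 5) {
  if (!nrow(grid)) return(list())
  n <- length(y)
  folds <- min(folds, n)
  fold_id <- rep_len(seq_len(folds), n)
  mse <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    hp <- grid_row_hyper(grid, gi)
    se <- 0
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      fit <- fit_quietly(algorithm, X[tr, , drop = FALSE], y[tr], hp)
      pred <- predict(fit, X[!tr, , drop = FALSE])
      se <- se + sum((pred - y[!tr])^2)
    }
    mse[gi] <- se / n
  }
  grid_row_hyper(grid, which.min(mse))
}

# degenerate training folds (constant target) fall back to the mean
# reference, with a single warning per loocv() call
fit_quietly <- function(algorithm, X, y, hyper) {
  if (algorithm != "mean_ref" && stats::sd(y) == 0) {
    return(fit_mean_reference(y))
  }
  fit_model(algorithm, X, y, hyper)
}

#' Leave-one-out cross-validation of a learner
#'
#' Each patient in turn is held out and predicted by a model trained on all
#' the others; held-out predictions are aggregated into MAE and RMSE.
#' Hyperparameters come from one of two tuning modes:
#' * `"nested"` (default): an inner k-fold grid search inside every LOOCV
#'   training fold — no selection leakage into the held-out patient.
#' * `"pretuned"`: one k-fold grid search on the full data fixes the
#'   hyperparameters, then LOOCV refits with them. This mirrors the common
#'   grid-search-then-LOOCV workflow and is far cheaper; its (small)
#'   selection leakage is documented in the methods vignette.
#'
#' @param algorithm one of `mean_ref`, `ols`, `ridge`, `lasso`, `tree`,
#'   `svr`.
#' @param X design matrix (n >= 3 rows).
#' @param y numeric target.
#' @param grid data.frame of hyperparameter candidates (one column per
#'   hyperparameter); defaults per algorithm. Ignored when `hyper` is given.
#' @param tuning `"nested"` or `"pretuned"`.
#' @param hyper optional fixed hyperparameters (skips tuning entirely).
#' @param inner_folds folds of the inner grid search.
#' @return An object of class `cv_result`: per-patient held-out
#'   `predictions`, `abs_errors`, `mae`, `rmse`, the algorithm id and the
#'   hyperparameters used.
#' @export
loocv <- function(algorithm, X, y, grid = NULL,
                  tuning = c("nested", "pretuned"), hyper = NULL,
                  inner_folds = 5) {
  algorithm <- match.arg(algorithm, model_algorithms)
  tuning <- match.arg(tuning)
  X <- check_xy(X, y)
  n <- length(y)
  if (n < 3) stopf("loocv needs at least 3 observations")
  if (is.null(grid)) grid <- default_grid(algorithm, X, y)
  degenerate_seen <- FALSE

  fixed <- hyper
  if (is.null(fixed) && tuning == "pretuned") {
    fixed <- inner_cv_select(algorithm, X, y, grid, inner_folds)
  }
  preds <- numeric(n)
  for (i in seq_len(n)) {
    tr_X <- X[-i, , drop = FALSE]
    tr_y <- y[-i]
    hp <- fixed %||%
      inner_cv_select(algorithm, tr_X, tr_y, grid, inner_folds)
    if (algorithm != "mean_ref" && stats::sd(tr_y) == 0) {
      degenerate_seen <- TRUE
    }
    fit <- fit_quietly(algorithm, tr_X, tr_y, hp)
    preds[i] <- predict(fit, X[i, , drop = FALSE])
  }
  if (degenerate_seen) {
    warnf("constant training target in some folds; mean prediction used")
  }
  m <- cv_metrics(preds, y)
  structure(list(algorithm = algorithm, predictions = preds, observed = y,
                 abs_errors = m$abs_errors, mae = m$mae, rmse = m$rmse,
                 hyper = fixed, tuning = tuning),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result: %s, n=%d, MAE=%.4g, RMSE=%.4g>\n",
              x$algorithm, length(x$predictions), x$mae, x$rmse))
  invisible(x)
}

#' Paired Wilcoxon comparison of absolute errors against the reference
#'
#' Two-sided Wilcoxon signed-rank test on the per-patient difference of
#' absolute prediction errors between a model and the mean reference (or
#' any other model), paired by patient.
#'
#' @param abs_errors_model,abs_errors_reference equal-length vectors of
#'   absolute errors, paired by patient.
#' @return The p-value. If every paired difference is zero the test is
#'   undefined and `1` is returned with a warning.
#' @export
compare_to_reference <- function(abs_errors_model, abs_errors_reference) {
  if (length(abs_errors_model) != length(abs_errors_reference)) {
    stopf("error vectors must be paired by patient")
  }
  d <- abs_errors_model - abs_errors_reference
  if (all(d == 0)) {
    warnf("all paired differences are zero; returning p = 1")
    return(1)
  }
  suppressWarnings(
    stats::wilcox.test(abs_errors_model, abs_errors_reference,
                       paired = TRUE)$p.value)
}

#' Lasso feature selection along a cross-validated penalty path
#'
#' Runs the lasso down a log-spaced penalty path from `lambda_max` (the
#' smallest penalty with an all-zero solution), picks the `lambda*` that
#' minimizes the mean cross-validated error, and returns the features with
#' nonzero coefficients there. Selection is performed separately for every
#' (arm, target) pair by the caller. If nothing is selected the caller
#' should fall back to intercept-only models (the reference measure); this
#' is signalled with a warning.
#'
#' @param X design matrix.
#' @param y numeric target.
#' @param cv_folds folds of the cross-validation (default 10).
#' @param n_lambda path length.
#' @param seed integer seed controlling the fold split.
#' @param arm,target optional labels recorded in the result.
#' @return list with `features` (selected names), `lambda` (`lambda*`),
#'   `coefficients` (nonzero coefficients at `lambda*`), `cv_error` and
#'   the labels.
#' @export
select_features_lasso <- function(X, y, cv_folds = 10, n_lambda = 100,
                                  seed = 1, arm = NA, target = NA) {
  X <- check_xy(X, y)
  cv <- withr::with_seed(derive_seed(seed, "lasso_cv"),
    glmnet::cv.glmnet(X, y, alpha = 1, nfolds = cv_folds,
                      nlambda = n_lambda, standardize = TRUE))
  lam <- cv$lambda.min
  cf <- as.matrix(stats::coef(cv, s = "lambda.min"))
  nz <- cf[-1, 1]
  nz <- nz[nz != 0]
  if (!length(nz)) {
    warnf("lasso selected no features%s; downstream models fall back to the reference measure",
          if (is.na(arm)) "" else sprintf(" (%s/%s)", arm, target))
  }
  list(features = names(nz), lambda = lam, coefficients = nz,
       cv_error = min(cv$cvm), arm = arm, target = target)
}
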