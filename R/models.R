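# Per-arm, per-target learners. Each fit_* returns a `model_fit` carrying
# the algorithm id, hyperparameters, fitted structure and any
# standardization constants (always computed from the training data only).
# Ridge and OLS are solved directly (QR / normal equations) so that the
# penalty parameterization is explicit: ridge minimizes
#   ||y - b0 - X b||^2 + lambda * ||b_std||^2
# with X standardized to unit SD and an unpenalized intercept, hence
# lambda = 0 reproduces OLS exactly. The lasso uses the coordinate-descent
# path of glmnet under the objective (1/2n)||y - b0 - X b||^2 + lambda|b|_1
# (standardized X, unpenalized intercept). Trees are CART variance-reduction
# trees (rpart); SVR is epsilon-insensitive support vector regression
# (e1071/libsvm).

model_algorithms <- c("mean_ref", "ols", "ridge", "lasso", "tree", "svr")

new_model_fit <- function(algorithm, fit, hyper = list(), standardization = NULL,
                          feature_names = NULL, arm = NA_character_,
                          target = NA_character_) {
  structure(list(algorithm = algorithm, fit = fit, hyper = hyper,
                 standardization = standardization,
                 feature_names = feature_names, arm = arm, target = target),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  hp <- if (length(x$hyper)) {
    paste(names(x$hyper), vapply(x$hyper, format, character(1)),
          sep = "=", collapse = ", ")
  } else "none"
  cat(sprintf("<model_fit: %s (%d features), hyper: %s>\n",
              x$algorithm, length(x$feature_names %||% character()), hp))
  invisible(x)
}

check_xy <- function(X, y) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stopf("X must be numeric")
  if (nrow(X) != length(y)) stopf("X and y dimensions disagree")
  if (anyNA(X) || anyNA(y)) stopf("X and y must be complete")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  X
}

# center/scale helper; zero-variance columns get scale 1 (their coefficient
# is then driven to 0 by the penalty or is irrelevant)
standardize_cols <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(center = ctr, scale = scl,
       Z = sweep(sweep(X, 2, ctr), 2, scl, "/"))
}

#' Mean reference model
#'
#' The intercept-only predictor: predicts the training mean of the target
#' for every input. All other learners are judged against it — if a method
#' cannot beat the mean, its added complexity buys nothing.
#'
#' @param y nonempty numeric target vector.
#' @return A `model_fit`.
#' @export
fit_mean_reference <- function(y) {
  if (!length(y) || anyNA(y)) stopf("y must be nonempty and complete")
  new_model_fit("mean_ref", fit = list(mean = mean(y)))
}

#' Ordinary least squares
#'
#' QR-based least squares with intercept. Requires fewer columns than rows
#' (with hundreds of baseline features this restricts OLS to
#' feature-selected designs). A rank-deficient design is solved by the
#' minimum-norm solution via the SVD pseudoinverse, with a warning.
#'
#' @param X design matrix (patients x features).
#' @param y numeric target.
#' @return A `model_fit` with intercept and coefficients.
#' @export
fit_ols <- function(X, y) {
  X <- check_xy(X, y)
  if (ncol(X) >= nrow(X)) {
    stopf("fit_ols requires fewer features (%d) than observations (%d)",
          ncol(X), nrow(X))
  }
  A <- cbind(`(Intercept)` = 1, X)
  qr_a <- qr(A)
  if (qr_a$rank < ncol(A)) {
    warnf("rank-deficient design; returning the minimum-norm solution")
    sv <- svd(A)
    pos <- sv$d > max(sv$d) * 1e-10
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
    beta <- drop(beta)
  } else {
    beta <- qr.coef(qr_a, y)
  }
  names(beta) <- colnames(A)
  new_model_fit("ols", fit = list(intercept = beta[1], coef = beta[-1]),
                feature_names = colnames(X))
}

#' Ridge regression
#'
#' Closed-form L2-penalized least squares on internally standardized
#' features with an unpenalized intercept:
#' minimize `||y - b0 - X b||^2 + lambda ||b_std||^2`. `lambda = 0` reduces
#' exactly to OLS; `lambda -> Inf` shrinks every slope to 0 so that the
#' prediction collapses to the training mean.
#'
#' @param X design matrix.
#' @param y numeric target.
#' @param lambda nonnegative penalty.
#' @return A `model_fit` with the standardization constants recorded.
#' @export
fit_ridge <- function(X, y, lambda) {
  X <- check_xy(X, y)
  if (!is_scalar_number(lambda) || lambda < 0) stopf("lambda must be >= 0")
  st <- standardize_cols(X)
  yc <- y - mean(y)
  p <- ncol(X)
  A <- crossprod(st$Z) + diag(lambda, p)
  b_std <- tryCatch(solve(A, crossprod(st$Z, yc)),
                    error = function(e) {
                      qr.coef(qr(rbind(st$Z, diag(sqrt(lambda), p))),
                              c(yc, rep(0, p)))
                    })
  b_std <- drop(b_std)
  b_std[is.na(b_std)] <- 0
  coef <- b_std / st$scale
  intercept <- mean(y) - sum(coef * st$center)
  new_model_fit("ridge", fit = list(intercept = intercept, coef = coef),
                hyper = list(lambda = lambda),
                standardization = st[c("center", "scale")],
                feature_names = colnames(X))
}

# smallest penalty at which every lasso slope is zero, under the
# (1/2n) * RSS + lambda * |b|_1 objective on standardized columns
# (standardization uses the 1/n variance, matching the objective's scaling)
lasso_lambda_max <- function(X, y) {
  X <- check_xy(X, y)
  xc <- sweep(X, 2, colMeans(X))
  scl <- sqrt(colMeans(xc^2))
  scl[scl == 0 | !is.finite(scl)] <- 1
  max(abs(crossprod(sweep(xc, 2, scl, "/"), y - mean(y)))) / nrow(X)
}

#' Lasso regression at a fixed penalty
#'
#' L1-penalized least squares, `(1/2n)||y - b0 - Xb||^2 + lambda |b|_1`,
#' solved by coordinate descent along a warm-started penalty path
#' (glmnet, convergence tolerance 1e-12) with standardized features and an
#' unpenalized intercept. The L1 penalty shrinks useless coefficients to
#' exactly zero, producing a sparse solution; at
#' `lambda >= max_j |x_j'(y - ybar)|/n` every slope is zero.
#'
#' @param X design matrix.
#' @param y numeric target.
#' @param lambda nonnegative penalty.
#' @return A `model_fit`; coefficients are on the original feature scale.
#' @export
fit_lasso <- function(X, y, lambda) {
  X <- check_xy(X, y)
  if (!is_scalar_number(lambda) || lambda < 0) stopf("lambda must be >= 0")
  lmax <- lasso_lambda_max(X, y)
  if (lmax == 0) {
    # constant target (or all-constant features): intercept-only solution
    return(new_model_fit("lasso",
                         fit = list(intercept = mean(y),
                                    coef = stats::setNames(rep(0, ncol(X)),
                                                           colnames(X))),
                         hyper = list(lambda = lambda),
                         feature_names = colnames(X)))
  }
  if (lambda >= lmax) {
    path <- c(lambda * 1.5, lambda)
  } else {
    path <- lmax * exp(seq(0, log(max(lambda, lmax * 1e-4) / lmax),
                           length.out = 30))
    path <- sort(unique(c(path, lambda)), decreasing = TRUE)
  }
  g <- glmnet::glmnet(X, y, alpha = 1, lambda = path, standardize = TRUE,
                      thresh = 1e-12, maxit = 1e6)
  cf <- as.numeric(stats::coef(g, s = lambda, exact = FALSE))
  new_model_fit("lasso",
                fit = list(intercept = cf[1],
                           coef = stats::setNames(cf[-1], colnames(X))),
                hyper = list(lambda = lambda), feature_names = colnames(X))
}

#' CART regression tree
#'
#' Binary regression tree grown by variance-reduction splits; each leaf
#' predicts its training mean.
#'
#' @param X design matrix.
#' @param y numeric target.
#' @param depth maximum tree depth (>= 1).
#' @param min_leaf minimum observations per leaf (>= 1).
#' @return A `model_fit` wrapping the tree.
#' @export
fit_tree <- function(X, y, depth = 3, min_leaf = 10) {
  X <- check_xy(X, y)
  check_count(depth, "depth", min = 1L)
  check_count(min_leaf, "min_leaf", min = 1L)
  df <- data.frame(.y = y, X, check.names = FALSE)
  fit <- rpart::rpart(
    .y ~ ., data = df,
    control = rpart::rpart.control(maxdepth = depth, minbucket = min_leaf,
                                   minsplit = max(2L, 2L * min_leaf),
                                   cp = 1e-6, xval = 0, maxsurrogate = 0,
                                   maxcompete = 0))
  new_model_fit("tree", fit = fit,
                hyper = list(depth = depth, min_leaf = min_leaf),
                feature_names = colnames(X))
}

#' Epsilon-insensitive support vector regression
#'
#' Wraps libsvm's eps-regression: training points inside the epsilon tube
#' incur no loss. Features and target are standardized internally from the
#' training data (the constants are recorded and inverted at prediction
#' time); `epsilon` is expressed in raw target units. A constant target
#' degenerates to a constant predictor.
#'
#' @param X design matrix.
#' @param y numeric target.
#' @param C cost parameter (> 0).
#' @param epsilon tube half-width in target units (>= 0).
#' @param kernel `"linear"` or `"radial"`.
#' @return A `model_fit` wrapping the support-vector machine.
#' @export
fit_svr <- function(X, y, C = 1, epsilon = 0.1,
                    kernel = c("radial", "linear")) {
  X <- check_xy(X, y)
  kernel <- kernel[1]
  if (!kernel %in% c("radial", "linear")) {
    stopf("invalid kernel '%s'; use 'radial' or 'linear'", kernel)
  }
  if (!is_scalar_number(C) || C <= 0) stopf("C must be > 0")
  if (!is_scalar_number(epsilon) || epsilon < 0) stopf("epsilon must be >= 0")
  st <- standardize_cols(X)
  y_center <- mean(y)
  y_scale <- stats::sd(y)
  if (!is.finite(y_scale) || y_scale == 0) {
    return(new_model_fit("svr", fit = list(constant = y_center),
                         hyper = list(C = C, epsilon = epsilon,
                                      kernel = kernel),
                         feature_names = colnames(X)))
  }
  fit <- e1071::svm(st$Z, (y - y_center) / y_scale, type = "eps-regression",
                    kernel = kernel, cost = C, epsilon = epsilon / y_scale,
                    scale = FALSE)
  new_model_fit("svr", fit = fit,
                hyper = list(C = C, epsilon = epsilon, kernel = kernel),
                standardization = c(st[c("center", "scale")],
                                    list(y_center = y_center,
                                         y_scale = y_scale)),
                feature_names = colnames(X))
}

#' Fit any of the registered learners
#'
#' Dispatch wrapper used by [loocv()] and the pipeline: `algorithm` is one
#' of `mean_ref`, `ols`, `ridge`, `lasso`, `tree`, `svr`, and `hyper` is a
#' named list of that learner's hyperparameters.
#'
#' @param algorithm algorithm id.
#' @param X design matrix.
#' @param y numeric target.
#' @param hyper named list of hyperparameters (ignored for `mean_ref`/`ols`).
#' @return A `model_fit`.
#' @export
fit_model <- function(algorithm, X, y, hyper = list()) {
  algorithm <- match.arg(algorithm, model_algorithms)
  switch(algorithm,
    mean_ref = fit_mean_reference(y),
    ols = fit_ols(X, y),
    ridge = fit_ridge(X, y, lambda = hyper$lambda %||% 1),
    lasso = fit_lasso(X, y, lambda = hyper$lambda %||% 0.01),
    tree = fit_tree(X, y, depth = hyper$depth %||% 3,
                    min_leaf = hyper$min_leaf %||% 10),
    svr = fit_svr(X, y, C = hyper$C %||% 1, epsilon = hyper$epsilon %||% 0.1,
                  kernel = hyper$kernel %||% "radial"))
}

#' Predict from a fitted model
#'
#' @param object a `model_fit`.
#' @param newdata numeric matrix with the columns the model was trained on;
#'   a missing column is an error naming the column.
#' @param ... unused.
#' @return Numeric predictions.
#' @export
predict.model_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (object$algorithm == "mean_ref") {
    return(rep(object$fit$mean, nrow(newdata)))
  }
  want <- object$feature_names
  have <- colnames(newdata)
  if (!is.null(want)) {
    if (is.null(have)) {
      if (ncol(newdata) != length(want)) {
        stopf("newdata has %d columns; model expects %d",
              ncol(newdata), length(want))
      }
      colnames(newdata) <- want
    } else {
      missing_cols <- setdiff(want, have)
      if (length(missing_cols)) {
        stopf("newdata lacks column(s): %s",
              paste(missing_cols, collapse = ", "))
      }
      newdata <- newdata[, want, drop = FALSE]
    }
  }
  switch(object$algorithm,
    ols = ,
    ridge = ,
    lasso = drop(object$fit$intercept + newdata %*% object$fit$coef),
    tree = unname(stats::predict(
      object$fit, data.frame(newdata, check.names = FALSE))),
    svr = {
      if (!is.null(object$fit$constant)) {
        rep(object$fit$constant, nrow(newdata))
      } else {
        st <- object$standardization
        Z <- sweep(sweep(newdata, 2, st$center), 2, st$scale, "/")
        unname(stats::predict(object$fit, Z)) * st$y_scale + st$y_center
      }
    })
}
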