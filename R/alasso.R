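# Adaptive LASSO by cyclic coordinate descent on the objective
#   sum_i (y_i - yhat_i)^2 + lambda * sum_j w_j |beta_j|
# with an unpenalized intercept.  Predictors are NOT internally
# re-standardized: scale is handled by the adaptive weights
# w_j = 1 / |beta_init_j|^gamma, so the objective above is minimized
# exactly as written.  A `standardize` option exists for sensitivity runs.

#' Soft-thresholding operator
#'
#' `S(a, b) = sign(a) * max(|a| - b, 0)`, the scalar solution of the
#' one-dimensional L1-penalized least-squares problem and the kernel of
#' every coordinate-descent update.
#'
#' @param a Numeric vector.
#' @param b Nonnegative threshold(s).
#' @return Thresholded values, same shape as `a`.
#' @export
soft_threshold <- function(a, b) {
  if (any(b < 0)) stop("threshold must be nonnegative", call. = FALSE)
  sign(a) * pmax(abs(a) - b, 0)
}

#' Initial coefficient estimates for the adaptive weights
#'
#' Ridge (default) or ordinary least squares estimates of the regression of
#' `y` on centered `x`; the adaptive penalty weights are derived from these.
#' Ridge with a small penalty is always finite, including for rank-deficient
#' designs.
#'
#' @param x Predictor matrix.
#' @param y Response vector.
#' @param method `"ridge"` or `"ols"`.
#' @param kappa Ridge penalty; default `0.01 * mean(colSums(xc^2))`, i.e.
#'   one percent of the average predictor sum of squares.
#' @return Named numeric vector of per-predictor estimates (no intercept).
#' @export
initial_estimates <- function(x, y, method = c("ridge", "ols"), kappa = NULL) {
  method <- match.arg(method)
  x <- as.matrix(x)
  xc <- scale(x, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  if (method == "ols") {
    qx <- qr(xc)
    if (qx$rank < ncol(xc))
      stop("design is rank-deficient; use method = \"ridge\"", call. = FALSE)
    b <- qr.coef(qx, yc)
  } else {
    if (is.null(kappa)) kappa <- 0.01 * mean(colSums(xc^2))
    b <- drop(solve(crossprod(xc) + diag(kappa, ncol(xc)), crossprod(xc, yc)))
  }
  names(b) <- colnames(x)
  b
}

#' Adaptive penalty weights
#'
#' `w_j = 1 / |beta_init_j|^gamma`.  A zero initial estimate yields an
#' infinite weight, which excludes that predictor at every lambda.  With
#' `gamma = 0` all weights are 1 (plain LASSO).
#'
#' @param beta_init Initial coefficient estimates.
#' @param gamma Nonnegative weight exponent (default 1).
#' @return Nonnegative (possibly infinite) weights, same names as
#'   `beta_init`.
#' @export
adaptive_weights <- function(beta_init, gamma = 1) {
  if (gamma < 0) stop("gamma must be >= 0", call. = FALSE)
  if (gamma == 0) {
    w <- rep(1, length(beta_init))
  } else {
    w <- ifelse(beta_init == 0, Inf, abs(beta_init)^(-gamma))
  }
  names(w) <- names(beta_init)
  w
}

# Smallest lambda at which every coefficient is zero:
# lambda_max = max_j 2 |x_j' (y - ybar)| / w_j over finite-weight j.
lambda_max_value <- function(xc, yc, weights) {
  fin <- is.finite(weights)
  if (!any(fin)) return(1)
  max(2 * abs(drop(crossprod(xc[, fin, drop = FALSE], yc))) / weights[fin])
}

make_lambda_path <- function(lambda_max, nlambda, ratio) {
  exp(seq(log(lambda_max), log(lambda_max * ratio), length.out = nlambda))
}

#' Weighted-L1 coordinate-descent solution path
#'
#' Solves the adaptive-LASSO objective down a descending lambda path by
#' cyclic coordinate descent with warm starts.  The path defaults to
#' `nlambda` geometrically spaced values from `lambda_max` (the smallest
#' lambda with all coefficients zero) down to `lambda_min_ratio *
#' lambda_max`.
#'
#' @param x Predictor matrix (not internally standardized).
#' @param y Response vector.
#' @param weights Nonnegative, possibly infinite penalty weights (one per
#'   column of `x`).
#' @param lambda Optional explicit descending lambda vector; overrides the
#'   generated path.
#' @param nlambda,lambda_min_ratio Path length and ratio of smallest to
#'   largest lambda.
#' @param tol Convergence tolerance on the maximum absolute coefficient
#'   change per sweep.
#' @param maxit Maximum coordinate-descent sweeps per lambda.
#' @return List of class `alasso_path`: `lambda`, coefficient matrix `beta`
#'   (p x length(lambda)), `intercept` per lambda, sweep counts.
#' @export
alasso_path <- function(x, y, weights, lambda = NULL, nlambda = 100,
                        lambda_min_ratio = 1e-3, tol = 1e-7, maxit = 1e6) {
  x <- as.matrix(x)
  if (length(weights) != ncol(x))
    stop("need one weight per predictor", call. = FALSE)
  if (any(weights < 0)) stop("weights must be nonnegative", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values in x or y", call. = FALSE)
  xm <- colMeans(x)
  xc <- sweep(x, 2, xm)
  ym <- mean(y)
  yc <- y - ym
  if (is.null(lambda)) {
    lmax <- lambda_max_value(xc, yc, weights)
    lambda <- make_lambda_path(lmax, nlambda, lambda_min_ratio)
  }
  fit <- cd_path(xc, yc, as.numeric(weights), as.numeric(lambda),
                 tol, as.integer(maxit))
  if (!all(fit$converged)) {
    l <- which(!fit$converged)[1]
    stop(sprintf("coordinate descent did not converge at lambda = %.6g (%d sweeps)",
                 lambda[l], fit$sweeps[l]), call. = FALSE)
  }
  beta <- fit$beta
  rownames(beta) <- colnames(x)
  intercept <- ym - drop(xm %*% beta)
  structure(list(lambda = lambda, beta = beta, intercept = intercept,
                 sweeps = fit$sweeps), class = "alasso_path")
}

#' Cross-validate the lambda path
#'
#' Rows are shuffled into `k` near-equal folds with a seeded permutation;
#' for each fold the path is refit on the remaining rows (with the same
#' penalty weights and lambda values) and held-out squared error is
#' accumulated.  `lambda_selected` minimizes mean CV MSE (rule `"min"`,
#' ties broken toward the larger, sparser lambda); rule `"1se"` takes the
#' largest lambda within one standard error of the minimum.
#'
#' @inheritParams alasso_path
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the fold shuffle.
#' @param lambda Descending lambda path to evaluate (required, so that all
#'   folds share it).
#' @param rule `"min"` or `"1se"`.
#' @return List: `lambda`, `cvm` (mean CV MSE per lambda), `cvse`
#'   (standard error over folds), `lambda_selected`, `index_selected`,
#'   `fold` assignment.
#' @export
cv_alasso <- function(x, y, weights, k = 10, seed = 1, lambda,
                      rule = c("min", "1se"), tol = 1e-7, maxit = 1e6) {
  rule <- match.arg(rule)
  x <- as.matrix(x)
  n <- nrow(x)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (k > n) stop("more folds than observations", call. = FALSE)
  set.seed(as.integer(seed))
  fold <- sample(rep(seq_len(k), length.out = n))
  L <- length(lambda)
  fold_mse <- matrix(NA_real_, k, L)
  for (f in seq_len(k)) {
    tr <- fold != f
    pf <- alasso_path(x[tr, , drop = FALSE], y[tr], weights, lambda = lambda,
                      tol = tol, maxit = maxit)
    pred <- x[!tr, , drop = FALSE] %*% pf$beta +
      matrix(pf$intercept, sum(!tr), L, byrow = TRUE)
    fold_mse[f, ] <- colMeans((y[!tr] - pred)^2)
  }
  nf <- tabulate(fold, k)
  cvm <- colSums(fold_mse * nf) / n          # weighted by fold size
  cvse <- apply(fold_mse, 2, sd) / sqrt(k)
  i_min <- which(cvm <= min(cvm))[1]         # path descends: first = largest
  i_sel <- if (rule == "min") i_min else
    which(cvm <= cvm[i_min] + cvse[i_min])[1]
  list(lambda = lambda, cvm = cvm, cvse = cvse,
       lambda_selected = lambda[i_sel], index_selected = i_sel,
       rule = rule, fold = fold)
}

#' Fit an adaptive LASSO regression
#'
#' The full adaptive-LASSO pipeline for one analysis dataset: initial
#' estimates (ridge by default), adaptive weights `w_j =
#' 1/|beta_init_j|^gamma`, k-fold cross-validation of the mean squared
#' error over a geometric lambda path, and a final coordinate-descent refit
#' on all rows at the selected lambda.  The objective is
#' `sum (y - yhat)^2 + lambda * sum w_j |beta_j|` with an unpenalized
#' intercept; predictors are used on their original scale unless
#' `standardize = TRUE`.
#'
#' @param x Predictor matrix (or a formula; see Details).
#' @param y Response vector.
#' @param gamma Adaptive-weight exponent (default 1; 0 gives plain LASSO).
#' @param init Initial-estimate method, `"ridge"` (default) or `"ols"`.
#' @param kappa Ridge penalty for the initial estimates (see
#'   [initial_estimates()]).
#' @param penalty_weights Optional explicit penalty weights, bypassing the
#'   initial fit.
#' @param nlambda,lambda_min_ratio Lambda path settings.
#' @param nfolds Cross-validation folds (default 10).
#' @param cv_rule Lambda selection rule, `"min"` (default) or `"1se"`.
#' @param standardize Standardize predictors to unit SD internally
#'   (coefficients are reported on the original scale); default `FALSE`.
#' @param seed Seed for the CV fold shuffle.
#' @param tol,maxit Coordinate-descent convergence controls (maximum
#'   absolute coefficient change per sweep; sweep cap).
#' @param ... Passed between methods.
#'
#' @details The formula method builds the design matrix with
#'   [stats::model.matrix()] (intercept column dropped) and dispatches to
#'   the default method.
#'
#' @return Object of class `adaptive_lasso`: initial estimates, weights,
#'   lambda path, full coefficient path, CV curve, selected lambda, and the
#'   intercept/coefficients of the final refit.  Supports `print()`,
#'   `summary()`, `coef()`, `predict()`, `residuals()` and `plot()`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200 * 5), 200, 5,
#'             dimnames = list(NULL, paste0("x", 1:5)))
#' y <- 2 * x[, 1] - x[, 3] + rnorm(200)
#' fit <- adaptive_lasso(x, y, seed = 1)
#' fit$nonzero
#' @export
adaptive_lasso <- function(x, ...) UseMethod("adaptive_lasso")

#' @rdname adaptive_lasso
#' @param formula,data Model formula and data frame for the formula method.
#' @export
adaptive_lasso.formula <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data)
  y <- model.response(mf)
  x <- model.matrix(attr(mf, "terms"), mf)
  x <- x[, colnames(x) != "(Intercept)", drop = FALSE]
  out <- adaptive_lasso.default(x, y, ...)
  out$terms <- attr(mf, "terms")
  out$call <- match.call()
  out
}

#' @rdname adaptive_lasso
#' @export
adaptive_lasso.default <- function(x, y, gamma = 1, init = c("ridge", "ols"),
                                   kappa = NULL, penalty_weights = NULL,
                                   nlambda = 100, lambda_min_ratio = 1e-3,
                                   nfolds = 10, cv_rule = c("min", "1se"),
                                   standardize = FALSE, seed = 1,
                                   tol = 1e-7, maxit = 1e6, ...) {
  init <- match.arg(init)
  cv_rule <- match.arg(cv_rule)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (nrow(x) < 2) stop("need at least 2 observations", call. = FALSE)

  sds <- rep(1, ncol(x))
  if (standardize) {
    sds <- apply(x, 2, sd)
    sds[sds == 0] <- 1
    x <- sweep(x, 2, sds, "/")
  }

  beta_init <- if (is.null(penalty_weights))
    initial_estimates(x, y, method = init, kappa = kappa) else NULL
  weights <- if (is.null(penalty_weights))
    adaptive_weights(beta_init, gamma) else penalty_weights

  xc <- scale(x, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  lmax <- lambda_max_value(xc, yc, weights)
  lambda <- make_lambda_path(lmax, nlambda, lambda_min_ratio)

  cv <- cv_alasso(x, y, weights, k = nfolds, seed = seed, lambda = lambda,
                  rule = cv_rule, tol = tol, maxit = maxit)
  path <- alasso_path(x, y, weights, lambda = lambda, tol = tol, maxit = maxit)

  i <- cv$index_selected
  beta <- path$beta[, i] / sds
  intercept <- path$intercept[i]
  fitted <- drop(as.matrix(x) %*% path$beta[, i]) + intercept

  structure(list(
    call = match.call(), n = nrow(x), p = ncol(x),
    beta_init = if (!is.null(beta_init)) beta_init / sds else NULL,
    gamma = gamma, weights = weights, standardize = standardize,
    lambda = lambda, path = path, cv = cv,
    lambda_selected = cv$lambda_selected,
    intercept = intercept, beta = beta,
    nonzero = names(beta)[beta != 0],
    y = y, fitted = fitted, seed = seed
  ), class = "adaptive_lasso")
}

#' @export
print.adaptive_lasso <- function(x, ...) {
  cat("Adaptive LASSO fit\n")
  cat(sprintf("  n = %d, p = %d, gamma = %g, %d-fold CV (rule '%s')\n",
              x$n, x$p, x$gamma, max(x$cv$fold), x$cv$rule))
  cat(sprintf("  lambda selected = %.5g; %d of %d predictors selected\n",
              x$lambda_selected, length(x$nonzero), x$p))
  if (length(x$nonzero)) {
    cat("  nonzero coefficients:\n")
    print(round(x$beta[x$beta != 0], 4))
  }
  invisible(x)
}

#' @export
summary.adaptive_lasso <- function(object, ...) {
  tab <- data.frame(predictor = names(object$beta),
                    weight = as.numeric(object$weights),
                    coefficient = as.numeric(object$beta),
                    selected = object$beta != 0,
                    row.names = NULL)
  out <- list(table = tab, lambda_selected = object$lambda_selected,
              cv_mse_min = min(object$cv$cvm), n = object$n,
              intercept = object$intercept)
  class(out) <- "summary.adaptive_lasso"
  out
}

#' @export
print.summary.adaptive_lasso <- function(x, ...) {
  cat(sprintf("Adaptive LASSO: lambda = %.5g, CV MSE = %.4g, intercept = %.4g\n",
              x$lambda_selected, x$cv_mse_min, x$intercept))
  print(x$table[x$table$selected, , drop = FALSE], row.names = FALSE)
  invisible(x)
}

#' @export
coef.adaptive_lasso <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$beta)
}

#' @export
predict.adaptive_lasso <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted)
  if (!is.null(object$terms) && is.data.frame(newdata)) {
    mm <- model.matrix(delete.response(object$terms), newdata)
    mm <- mm[, colnames(mm) != "(Intercept)", drop = FALSE]
  } else {
    mm <- as.matrix(newdata)
  }
  drop(mm[, names(object$beta), drop = FALSE] %*% object$beta) + object$intercept
}

#' @export
residuals.adaptive_lasso <- function(object, ...) {
  object$y - object$fitted
}

#' Plot an adaptive LASSO fit
#'
#' `type = "cv"` draws the cross-validation MSE curve (with +/- 1 SE band)
#' against log lambda; `type = "path"` draws the coefficient paths.  The
#' selected lambda is marked in both.
#'
#' @param x An `adaptive_lasso` fit.
#' @param type `"cv"` or `"path"`.
#' @param ... Passed to the underlying plot call.
#' @export
plot.adaptive_lasso <- function(x, type = c("cv", "path"), ...) {
  type <- match.arg(type)
  ll <- log(x$lambda)
  if (type == "cv") {
    cv <- x$cv
    plot(ll, cv$cvm, type = "l", xlab = "log(lambda)", ylab = "CV MSE", ...)
    graphics::lines(ll, cv$cvm + cv$cvse, lty = 3)
    graphics::lines(ll, cv$cvm - cv$cvse, lty = 3)
  } else {
    graphics::matplot(ll, t(x$path$beta), type = "l", lty = 1,
                      xlab = "log(lambda)", ylab = "coefficient", ...)
  }
  graphics::abline(v = log(x$lambda_selected), lty = 2)
  invisible(x)
}
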