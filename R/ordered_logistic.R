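# Proportional-odds (cumulative-logit) maximum likelihood, written for the
# chained-equations imputation loop: handles K = 2 (plain logistic) through
# K = 7, returns the asymptotic covariance needed for proper-imputation
# parameter draws, and falls back to a ridge-stabilized fit under
# separation or non-convergence.
#
# Internal parameterization is unconstrained: theta = (z1, g_2..g_{K-1},
# beta) with cutpoints zeta_k = z1 + sum_{j<=k} exp(g_j), which keeps the
# cutpoints strictly ascending during optimization and makes Gaussian
# perturbation draws in theta-space always yield a valid model.
# Model: P(Y <= k | x) = plogis(zeta_k - x'beta).

theta_to_zeta <- function(theta, K) {
  if (K == 2) return(theta[1])
  theta[1] + cumsum(c(0, exp(theta[2:(K - 1)])))
}

# a_i = zeta_{y_i} - eta_i (upper cut; +Inf for the top category) and
# b_i = zeta_{y_i - 1} - eta_i (lower cut; -Inf for the bottom one),
# built by indexing the padded cutpoint vector; dlogis(+-Inf) = 0 so the
# boundary categories fall out of the gradient automatically.
ordlog_nll <- function(theta, X, yk, K, ridge) {
  p <- ncol(X)
  zeta <- theta_to_zeta(theta, K)
  beta <- if (p) theta[(K - 1) + seq_len(p)] else numeric(0)
  eta <- if (p) drop(X %*% beta) else 0
  a <- c(zeta, Inf)[yk] - eta
  b <- c(-Inf, zeta)[yk] - eta
  P <- pmax(plogis(a) - plogis(b), 1e-300)
  -sum(log(P)) + ridge / 2 * sum(beta^2)
}

ordlog_grad <- function(theta, X, yk, K, ridge) {
  p <- ncol(X)
  zeta <- theta_to_zeta(theta, K)
  beta <- if (p) theta[(K - 1) + seq_len(p)] else numeric(0)
  eta <- if (p) drop(X %*% beta) else 0
  a <- c(zeta, Inf)[yk] - eta
  b <- c(-Inf, zeta)[yk] - eta
  P <- pmax(plogis(a) - plogis(b), 1e-300)
  u <- dlogis(a) / P    #  d logP / d a
  v <- dlogis(b) / P    # -d logP / d b
  # d nll / d zeta_k: category k contributes through its upper cut,
  # category k+1 through its lower cut
  dz <- -(rowsum_by(u, yk, K)[seq_len(K - 1)] -
            rowsum_by(v, yk, K)[2:K])
  g1 <- sum(dz)
  gg <- if (K > 2) exp(theta[2:(K - 1)]) * rev(cumsum(rev(dz)))[-1] else numeric(0)
  gbeta <- if (p) drop(crossprod(X, u - v)) + ridge * beta else numeric(0)
  c(g1, gg, gbeta)
}

# sum of x within each category 1..K (fast tapply)
rowsum_by <- function(x, g, K) {
  out <- numeric(K)
  s <- rowsum(x, g)
  out[as.integer(rownames(s))] <- s
  out
}

#' Fit a proportional-odds (ordered logistic) regression
#'
#' Maximum-likelihood cumulative-logit fit `P(Y <= k | x) =
#' plogis(cutpoint_k - x'slopes)` by BFGS with analytic gradient.  With two
#' response categories this is exactly binary logistic regression.  If the
#' unpenalized fit does not converge or produces non-finite estimates
#' (e.g. separation), the fit is retried with a small ridge penalty on the
#' slopes and flagged.
#'
#' @param X Numeric matrix of predictors (no intercept column; may have
#'   zero columns for an intercept-only model).
#' @param y Ordinal response: integer codes or a factor; must show at least
#'   2 distinct categories.
#' @param ridge Optional ridge penalty on slopes (default 0; the fallback
#'   uses 1e-2 per observation).
#' @return List of class `ordered_logistic` with `cutpoints` (ascending,
#'   length K-1), `slopes`, `levels` (original category labels), `theta`
#'   and `vcov` in the unconstrained parameterization (for perturbation
#'   draws), `logLik`, `converged` and `ridge_used`.
#' @export
fit_ordered_logistic <- function(X, y, ridge = 0) {
  X <- as.matrix(X)
  if (is.factor(y)) y <- droplevels(y)
  lev <- if (is.factor(y)) levels(y) else sort(unique(y))
  K <- length(lev)
  if (K < 2) stop("response has fewer than 2 observed categories", call. = FALSE)
  yk <- match(if (is.factor(y)) as.character(y) else y, lev)
  if (nrow(X) != length(yk)) stop("nrow(X) != length(y)", call. = FALSE)
  if (anyNA(X)) stop("X has missing entries", call. = FALSE)
  p <- ncol(X)

  # start: cutpoints from marginal cumulative proportions, zero slopes
  cum <- cumsum(tabulate(yk, K))[seq_len(K - 1)] / length(yk)
  cum <- pmin(pmax(cum, 1e-4), 1 - 1e-4)
  zeta0 <- qlogis(cum)
  zeta0 <- zeta0 + cumsum(c(0, pmax(1e-3 - diff(zeta0), 0)))  # enforce gaps
  start <- c(zeta0[1],
             if (K > 2) log(pmax(diff(zeta0), 1e-3)),
             rep(0, p))

  run <- function(rdg) {
    opt <- optim(start, ordlog_nll, ordlog_grad, X = X, yk = yk, K = K,
                 ridge = rdg, method = "BFGS",
                 control = list(maxit = 300, reltol = 1e-10))
    opt
  }
  slope_of <- function(par) if (p) par[(K - 1) + seq_len(p)] else numeric(0)
  ridge_used <- ridge
  opt <- run(ridge)
  # huge slopes signal (quasi-)separation: the likelihood plateaus and BFGS
  # "converges" on a diverging ray
  ok <- opt$convergence == 0 && all(is.finite(opt$par)) &&
    all(abs(opt$par) < 50) && all(abs(slope_of(opt$par)) < 10)
  if (!ok) {
    ridge_used <- max(ridge, 1e-2 * length(yk))
    opt <- run(ridge_used)
  }

  H <- tryCatch(
    optimHess(opt$par, ordlog_nll, ordlog_grad, X = X, yk = yk, K = K,
              ridge = ridge_used),
    error = function(e) NULL)
  V <- NULL
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V) && any(!is.finite(V))) V <- NULL
  }
  if (is.null(V)) V <- diag(1e-6, length(opt$par))

  structure(list(
    cutpoints = theta_to_zeta(opt$par, K),
    slopes = if (p) opt$par[(K - 1) + seq_len(p)] else numeric(0),
    levels = lev, K = K, theta = opt$par, vcov = V,
    logLik = -opt$value, converged = opt$convergence == 0,
    ridge_used = ridge_used
  ), class = "ordered_logistic")
}

# Category probabilities (n x K) for an unconstrained parameter vector.
ordlog_probs <- function(theta, X, K) {
  X <- as.matrix(X)
  p <- ncol(X)
  zeta <- theta_to_zeta(theta, K)
  eta <- if (p) drop(X %*% theta[(K - 1) + seq_len(p)]) else rep(0, nrow(X))
  cdf <- cbind(0, plogis(outer(-eta, zeta, "+")), 1)
  pr <- cdf[, -1, drop = FALSE] - cdf[, -(K + 1), drop = FALSE]
  pr[pr < 0] <- 0
  pr / rowSums(pr)
}

#' @export
print.ordered_logistic <- function(x, ...) {
  cat(sprintf("Proportional-odds fit: %d categories, %d slope(s)%s\n",
              x$K, length(x$slopes),
              if (x$ridge_used > 0) sprintf(" [ridge %.3g]", x$ridge_used) else ""))
  cat("cutpoints:", format(x$cutpoints, digits = 4), "\n")
  if (length(x$slopes)) cat("slopes:   ", format(x$slopes, digits = 4), "\n")
  invisible(x)
}
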