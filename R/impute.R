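# Chained-equations multiple imputation for the ordinal weekly stress
# panel.  Each week with missingness gets a proportional-odds conditional
# model whose predictors are the neighboring weeks (within +/- 3) of the
# current completed panel plus the person mean of each participant's
# originally observed weeks.  Parameter draws from the asymptotic normal of
# the fit make the imputation approximately proper.

#' Complete a stress panel once by chained-equations ordinal imputation
#'
#' Missing weekly cells (including post-parturition weeks, so every
#' participant ends up on the full 15-41 grid) are initialized by draws
#' from each week's observed marginal distribution, then refined over
#' `n_burnin` chained-equation cycles.  In each cycle, every week with
#' missingness is regressed (proportional-odds) on its neighboring weeks
#' within `neighbor_window` and on the person mean of originally observed
#' values; model parameters are perturbed by a draw from their asymptotic
#' normal before each missing cell is drawn from the implied category
#' distribution.  Observed cells are never altered.
#'
#' @param panel Long stress panel with missing cells.
#' @param seed Integer seed for this completion.
#' @param n_burnin Number of chained-equation cycles (default 10).
#' @param neighbor_window Half-width of the week window used as predictors
#'   (default 3).
#' @return Completed long panel (no missing cells), with attributes
#'   `imputation_seed` and `impute_log` (per-week convergence/fallback flags
#'   from the final cycle).
#' @export
impute_once <- function(panel, seed, n_burnin = 10, neighbor_window = 3) {
  W <- panel_to_matrix(panel)
  weeks <- as.integer(colnames(W))
  obs <- !is.na(W)
  if (!any(!obs)) {
    out <- panel
    attr(out, "imputation_seed") <- seed
    attr(out, "impute_log") <- data.frame(week = integer(0))
    return(out)
  }
  nobs_week <- colSums(obs)
  if (any(nobs_week == 0))
    stop(sprintf("week(s) %s have no observed values; cannot impute",
                 paste(weeks[nobs_week == 0], collapse = ", ")), call. = FALSE)

  set.seed(as.integer(seed))
  # person mean of originally observed cells; grand mean for all-missing rows
  pm_obs <- rowMeans(W, na.rm = TRUE)
  pm_obs[!is.finite(pm_obs)] <- mean(W, na.rm = TRUE)

  # initialize from each week's observed marginal
  for (j in which(colSums(!obs) > 0)) {
    miss <- !obs[, j]
    W[miss, j] <- sample(W[obs[, j], j], sum(miss), replace = TRUE)
  }

  miss_weeks <- which(colSums(!obs) > 0)
  log_rows <- vector("list", length(miss_weeks))
  for (cycle in seq_len(n_burnin)) {
    for (m in seq_along(miss_weeks)) {
      j <- miss_weeks[m]
      nb <- setdiff(which(abs(weeks - weeks[j]) <= neighbor_window), j)
      X <- cbind(W[, nb, drop = FALSE], pm = pm_obs)
      oj <- obs[, j]
      yobs <- W[oj, j]
      lev <- sort(unique(yobs))
      if (length(lev) < 2) {
        W[!oj, j] <- lev  # degenerate week: one observed category
        log_rows[[m]] <- data.frame(week = weeks[j], converged = TRUE,
                                    ridge_used = 0, degenerate = TRUE)
        next
      }
      fit <- fit_ordered_logistic(X[oj, , drop = FALSE], yobs)
      theta <- draw_mvn(fit$theta, fit$vcov)
      pr <- ordlog_probs(theta, X[!oj, , drop = FALSE], fit$K)
      draw <- apply(pr, 1, function(p) sample.int(fit$K, 1, prob = p))
      W[!oj, j] <- lev[draw]
      log_rows[[m]] <- data.frame(week = weeks[j], converged = fit$converged,
                                  ridge_used = fit$ridge_used, degenerate = FALSE)
    }
  }

  out <- matrix_to_panel(W)
  attr(out, "imputation_seed") <- seed
  attr(out, "impute_log") <- do.call(rbind, log_rows)
  out
}

# one draw from N(mu, Sigma); falls back to independent draws if the
# covariance is not positive definite
draw_mvn <- function(mu, Sigma) {
  R <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(R)) {
    s <- sqrt(pmax(diag(Sigma), 0))
    return(mu + rnorm(length(mu)) * s)
  }
  mu + drop(rnorm(length(mu)) %*% R)
}

#' Multiply impute a stress panel
#'
#' Produces `m` independent completions of the panel with seeds
#' `base_seed + 1, ..., base_seed + m`.  Observed cells are identical
#' across all completions.
#'
#' @param panel Long stress panel with missing cells.
#' @param m Number of imputations (default 21).
#' @param base_seed Integer base seed.
#' @param ... Passed to [impute_once()].
#' @return List of `m` completed panels (class `completed_panels`).
#' @export
multiply_impute <- function(panel, m = 21, base_seed = 0, ...) {
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  out <- lapply(seq_len(m), function(k)
    impute_once(panel, seed = base_seed + k, ...))
  structure(out, class = "completed_panels", m = m, base_seed = base_seed)
}

#' @export
print.completed_panels <- function(x, ...) {
  cat(sprintf("%d completed stress panel(s), base seed %s\n",
              attr(x, "m"), attr(x, "base_seed")))
  invisible(x)
}
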