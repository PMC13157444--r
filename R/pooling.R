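# Pooling of per-imputation adaptive-LASSO fits by selection frequency:
# a predictor is retained when it receives a nonzero coefficient in at
# least `threshold` of the m imputed datasets (default floor(m/2), i.e.
# the 10-of-21 rule at m = 21); pooled coefficients are averages across
# imputations and effect sizes rescale them by SD(predictor)/SD(outcome).

#' Selection counts across imputation fits
#'
#' For each predictor, the number of fits in which its coefficient is
#' nonzero.
#'
#' @param fits List of [adaptive_lasso()] fits sharing the same predictors
#'   in the same order.
#' @return Named integer vector of counts.
#' @export
selection_counts <- function(fits) {
  nm <- names(fits[[1]]$beta)
  for (f in fits) {
    if (!identical(names(f$beta), nm))
      stop("fits do not share an identical predictor set/order", call. = FALSE)
  }
  counts <- Reduce(`+`, lapply(fits, function(f) as.integer(f$beta != 0)))
  names(counts) <- nm
  counts
}

#' Predictors retained by the selection-frequency rule
#'
#' @param counts Named selection counts (see [selection_counts()]).
#' @param m Number of imputations.
#' @param threshold Minimum count for retention; default `floor(m/2)`,
#'   which reproduces the 10-of-21 rule at `m = 21`.
#' @return Character vector of retained predictor names.
#' @export
retain_predictors <- function(counts, m, threshold = floor(m / 2)) {
  if (threshold < 1) stop("threshold must be >= 1", call. = FALSE)
  if (any(counts < 0 | counts > m)) stop("counts must lie in 0..m", call. = FALSE)
  names(counts)[counts >= threshold]
}

#' Pooled coefficient of a retained predictor
#'
#' Averages the predictor's coefficient over the `m` fits.  Policy
#' `"all"` (default) includes the zeros from fits that did not select it —
#' the literal average over all imputed datasets; `"selected_only"`
#' averages over the selecting fits only.
#'
#' @param fits List of [adaptive_lasso()] fits.
#' @param predictor Predictor name.
#' @param policy `"all"` or `"selected_only"`.
#' @param threshold Retention threshold (default `floor(length(fits)/2)`);
#'   coefficients are only reported for retained predictors.
#' @return Scalar pooled coefficient.
#' @export
pooled_coefficient <- function(fits, predictor,
                               policy = c("all", "selected_only"),
                               threshold = floor(length(fits) / 2)) {
  policy <- match.arg(policy)
  b <- vapply(fits, function(f) f$beta[[predictor]], numeric(1))
  if (sum(b != 0) < threshold)
    stop(sprintf("'%s' was not retained (selected %d of %d times); coefficients are pooled for retained predictors only",
                 predictor, sum(b != 0), length(fits)), call. = FALSE)
  if (policy == "all") mean(b) else mean(b[b != 0])
}

#' Standardized effect size
#'
#' Rescales an unstandardized pooled coefficient by the ratio of predictor
#' SD to outcome SD.
#'
#' @param pooled_b Pooled unstandardized coefficient.
#' @param sd_predictor,sd_outcome Standard deviations (here: within-dataset
#'   sample SDs averaged over the m analysis datasets).
#' @return Scalar standardized effect.
#' @export
standardized_effect <- function(pooled_b, sd_predictor, sd_outcome) {
  if (sd_outcome <= 0) stop("sd_outcome must be > 0", call. = FALSE)
  pooled_b * sd_predictor / sd_outcome
}

#' Split participants into ACEs subgroups
#'
#' @param outcomes Outcome table with `participant_id` and `aces_count`.
#' @param aces_threshold High-ACEs cutoff (default 4, the conventional
#'   high-risk cut-point).
#' @return List of participant-id vectors `full`, `aces_high`
#'   (count >= threshold) and `aces_low` (count < threshold).  Participants
#'   with missing ACEs counts appear in `full` only.
#' @export
split_aces_groups <- function(outcomes, aces_threshold = 4) {
  aces <- outcomes$aces_count
  groups <- list(
    full = outcomes$participant_id,
    aces_high = outcomes$participant_id[!is.na(aces) & aces >= aces_threshold],
    aces_low = outcomes$participant_id[!is.na(aces) & aces < aces_threshold]
  )
  for (g in names(groups)) {
    if (length(groups[[g]]) == 0)
      stop(sprintf("subgroup '%s' is empty", g), call. = FALSE)
  }
  groups
}

#' Run the selection models across imputations, subgroups and outcomes
#'
#' For each requested sample (full cohort, high-ACEs, low-ACEs) and outcome
#' (depressive, anxiety), fits one adaptive LASSO per imputed dataset on
#' the 29 stress predictors, then pools: selection counts, retention by the
#' frequency rule, pooled coefficients (retained predictors only) and
#' standardized effect sizes.
#'
#' @param completed List of completed panels (from [multiply_impute()]).
#' @param outcomes Outcome table.
#' @param samples Subset of `c("full", "aces_high", "aces_low")`.
#' @param outcome_set Subset of `c("depressive", "anxiety")`.
#' @param aces_threshold High-ACEs cutoff (default 4).
#' @param retention_threshold Retention rule; default `floor(m/2)`.
#' @param policy Coefficient-averaging policy (see [pooled_coefficient()]).
#' @param seed Base seed; fit `k` of each model uses `seed + k` for its CV
#'   fold shuffle.
#' @param ... Further arguments to [adaptive_lasso()] (e.g. `gamma`,
#'   `nfolds`, `cv_rule`).
#' @return Object of class `stress_selection_report`: a long table (one row
#'   per model x predictor) plus settings; `print()` renders a
#'   selection-count table per model, `as.data.frame()` returns the table.
#' @export
run_stress_models <- function(completed, outcomes,
                              samples = c("full", "aces_high", "aces_low"),
                              outcome_set = c("depressive", "anxiety"),
                              aces_threshold = 4,
                              retention_threshold = NULL,
                              policy = c("all", "selected_only"),
                              seed = 1, ...) {
  policy <- match.arg(policy)
  samples <- match.arg(samples, several.ok = TRUE)
  outcome_set <- match.arg(outcome_set, several.ok = TRUE)
  m <- length(completed)
  if (m < 1) stop("need at least one completed dataset", call. = FALSE)
  thr <- if (is.null(retention_threshold)) floor(m / 2) else retention_threshold
  groups <- split_aces_groups(outcomes, aces_threshold)
  preds <- predictor_names()

  rows <- list()
  sizes <- list()
  for (s in samples) {
    ids <- groups[[s]]
    for (oc in outcome_set) {
      ocol <- outcome_column(oc)
      fits <- vector("list", m)
      sdx <- matrix(NA_real_, m, length(preds))
      sdy <- numeric(m)
      for (k in seq_len(m)) {
        pk <- completed[[k]]
        fm <- build_feature_matrix(pk[pk$participant_id %in% ids, , drop = FALSE],
                                   outcomes, oc)
        if (nrow(fm) < 2)
          stop(sprintf("model %s/%s: fewer than 2 participants with outcomes", s, oc),
               call. = FALSE)
        X <- as.matrix(fm[, preds])
        yv <- fm[[ocol]]
        fits[[k]] <- adaptive_lasso(X, yv, seed = seed + k, ...)
        sdx[k, ] <- apply(X, 2, sd)
        sdy[k] <- sd(yv)
      }
      counts <- selection_counts(fits)
      retained <- retain_predictors(counts, m, thr)
      coefs <- effs <- rep(NA_real_, length(preds))
      names(coefs) <- names(effs) <- preds
      msdx <- colMeans(sdx)
      msdy <- mean(sdy)
      for (p in retained) {
        coefs[p] <- pooled_coefficient(fits, p, policy, thr)
        effs[p] <- standardized_effect(coefs[p], msdx[match(p, preds)], msdy)
      }
      rows[[paste(s, oc)]] <- data.frame(
        sample = s, outcome = oc, predictor = preds,
        selection_count = as.integer(counts),
        retained = preds %in% retained,
        coefficient = as.numeric(coefs),
        effect_size = as.numeric(effs),
        n = fits[[1]]$n,
        row.names = NULL, stringsAsFactors = FALSE)
      sizes[[paste(s, oc)]] <- fits[[1]]$n
    }
  }
  structure(list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 m = m, threshold = thr, policy = policy,
                 aces_threshold = aces_threshold, seed = seed),
            class = "stress_selection_report")
}

#' @export
as.data.frame.stress_selection_report <- function(x, ...) x$table

#' @export
print.stress_selection_report <- function(x, ...) {
  cat(sprintf("Selection-frequency report: m = %d imputations, retained if selected in >= %d\n",
              x$m, x$threshold))
  tab <- x$table
  for (key in unique(paste(tab$sample, tab$outcome))) {
    sub <- tab[paste(tab$sample, tab$outcome) == key, ]
    cat(sprintf("\n%s outcome, %s sample (n = %d)\n",
                sub$outcome[1], sub$sample[1], sub$n[1]))
    line <- sprintf("%-6s count %2d%s", sub$predictor, sub$selection_count,
                    ifelse(sub$retained,
                           sprintf("  b = %6.3f  beta* = %6.3f",
                                   sub$coefficient, sub$effect_size), ""))
    cat(paste(line[sub$retained | sub$selection_count > 0], collapse = "\n"), "\n")
  }
  invisible(x)
}
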