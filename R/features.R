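#' Person mean of weekly stress
#'
#' Arithmetic mean of the available weekly values; the within-person
#' reference level that the weekly deviation scores are centered on.
#'
#' @param values Numeric vector of weekly stress scores (NA = missing).
#' @return Scalar mean.
#' @export
person_mean <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) == 0) stop("person_mean: no observed values", call. = FALSE)
  mean(v)
}

#' Person standard deviation of weekly stress
#'
#' Sample SD (denominator n - 1) of the available weekly values; the
#' within-person fluctuation predictor.
#'
#' @param values Numeric vector of weekly stress scores (NA = missing).
#' @return Scalar SD.
#' @export
person_sd <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2) stop("person_sd: need at least 2 observed values", call. = FALSE)
  sd(v)
}

#' Person-mean-centered weekly deviation scores
#'
#' `dev_w = x_w - mean`, expressing each week's stress relative to the
#' participant's own mean; deviations computed against the mean of the same
#' weeks sum to zero.
#'
#' @param values Numeric vector of weekly stress scores.
#' @param mean Person mean computed over the same weeks (defaults to
#'   [person_mean()] of `values`).
#' @return Numeric vector of deviations, same length and names as `values`.
#' @export
deviation_scores <- function(values, mean = person_mean(values)) {
  values - mean
}

#' Build the 29-predictor stress feature matrix for one outcome
#'
#' From a *completed* weekly panel (every participant observed on the full
#' week 15-41 grid, i.e. post-imputation) computes, per participant, the
#' person mean `M`, person SD `SD` and the 27 weekly deviation scores
#' `dev15..dev41`, and joins the named postpartum outcome.  Participants
#' missing that outcome are dropped.
#'
#' @param panel Completed long panel (`participant_id, gestational_week,
#'   stress`, no missing cells on the grid).
#' @param outcomes Outcome table (`participant_id, aces_count, epds_total,
#'   stai_total`).
#' @param outcome `"depressive"` (EPDS) or `"anxiety"` (STAI-state).
#' @return Data frame with columns `participant_id`, the 29 predictors in
#'   fixed order, and the outcome column; zero rows (with a warning) if no
#'   participant has the outcome.
#' @export
build_feature_matrix <- function(panel, outcomes, outcome = c("depressive", "anxiety")) {
  outcome <- match.arg(outcome)
  W <- panel_to_matrix(panel)
  if (anyNA(W))
    stop("panel has missing weekly cells; run imputation first", call. = FALSE)

  M <- rowMeans(W)
  SD <- apply(W, 1, sd)
  dev <- W - M
  colnames(dev) <- paste0("dev", WEEK_GRID)
  fm <- data.frame(participant_id = rownames(W), M = M, SD = SD, dev,
                   row.names = NULL, stringsAsFactors = FALSE,
                   check.names = FALSE)

  ocol <- outcome_column(outcome)
  y <- outcomes[[ocol]][match(fm$participant_id, outcomes$participant_id)]
  fm[[ocol]] <- y
  keep <- !is.na(y)
  if (!any(keep)) {
    warning(sprintf("no participant has an observed %s outcome; empty feature matrix",
                    outcome))
  }
  fm[keep, , drop = FALSE]
}

# Long panel -> participants x weeks matrix on the full 15-41 grid.
# Row order follows first appearance in the panel; absent (id, week)
# combinations become NA.
panel_to_matrix <- function(panel) {
  stopifnot(all(c("participant_id", "gestational_week", "stress") %in% names(panel)))
  if (!all(panel$gestational_week %in% WEEK_GRID))
    stop("gestational weeks outside the 15-41 grid", call. = FALSE)
  id <- unique(panel$participant_id)
  W <- matrix(NA_real_, length(id), length(WEEK_GRID),
              dimnames = list(id, WEEK_GRID))
  W[cbind(match(panel$participant_id, id),
          match(panel$gestational_week, WEEK_GRID))] <- panel$stress
  W
}

# participants x weeks matrix -> long panel
matrix_to_panel <- function(W) {
  data.frame(
    participant_id = rep(rownames(W), each = ncol(W)),
    gestational_week = rep(as.integer(colnames(W)), times = nrow(W)),
    stress = as.integer(t(W)),
    stringsAsFactors = FALSE
  )
}
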