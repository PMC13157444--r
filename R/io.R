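# File interchange and end-to-end orchestration.  Missing cells are empty
# CSV fields (never sentinel numbers: an ordinal 0 is a legal score).

#' Published per-model selection counts
#'
#' The selection counts (number of imputed datasets, out of 21, in which
#' each of the 29 stress predictors received a nonzero adaptive-LASSO
#' coefficient) as published for the six reference models: full sample,
#' high-ACEs and low-ACEs subgroups, for postpartum depressive and anxiety
#' symptoms.  Applying [retain_predictors()] with the 10-of-21 rule to
#' these counts reproduces the published retained sets.
#'
#' @return Data frame with columns `sample`, `outcome`, `predictor`,
#'   `selection_count`.
#' @export
published_selection_counts <- function() {
  read.csv(system.file("extdata", "published_selection_counts.csv",
                       package = "perilasso"),
           stringsAsFactors = FALSE)
}

#' Read a long-format weekly stress panel
#'
#' Expects header `participant_id, gestational_week, stress`; blank stress
#' fields are missing values.  Rows with weeks outside 15-41, stress
#' outside 0-6 or non-integer values, and duplicate (participant, week)
#' pairs are rejected with their row numbers.
#'
#' @param path CSV file path.
#' @return Validated panel data frame.
#' @export
read_weekly_stress <- function(path) {
  d <- read.csv(path, colClasses = c("character", "integer", "numeric"),
                stringsAsFactors = FALSE)
  need <- c("participant_id", "gestational_week", "stress")
  if (!identical(names(d), need))
    stop(sprintf("expected header '%s'", paste(need, collapse = ", ")), call. = FALSE)
  bad_week <- which(is.na(d$gestational_week) |
                      !(d$gestational_week %in% WEEK_GRID))
  s <- d$stress
  bad_stress <- which(!is.na(s) & (s < 0 | s > 6 | s != round(s)))
  dup <- which(duplicated(d[c("participant_id", "gestational_week")]))
  problems <- c(
    if (length(bad_week)) sprintf("week outside 15-41 at data row(s) %s",
                                  paste(bad_week, collapse = ", ")),
    if (length(bad_stress)) sprintf("stress outside integer 0-6 at data row(s) %s",
                                    paste(bad_stress, collapse = ", ")),
    if (length(dup)) sprintf("duplicate (participant, week) at data row(s) %s",
                             paste(dup, collapse = ", ")))
  if (length(problems))
    stop(paste0("invalid weekly stress file:\n  ",
                paste(problems, collapse = "\n  ")), call. = FALSE)
  d$stress <- as.integer(d$stress)
  d
}

#' Write a weekly stress panel
#' @param panel Panel data frame.
#' @param path Output CSV path.
#' @export
write_weekly_stress <- function(panel, path) {
  write.csv(panel[c("participant_id", "gestational_week", "stress")],
            path, row.names = FALSE, na = "")
}

#' Read the outcomes table
#'
#' Expects header `participant_id, aces_count, epds_total, stai_total`
#' (blanks = missing).  ACEs counts are validated to 0-10, EPDS totals to
#' 0-30 and STAI-state totals to 20-80, all integer.
#'
#' @param path CSV file path.
#' @return Validated outcomes data frame.
#' @export
read_outcomes <- function(path) {
  d <- read.csv(path, colClasses = c("character", rep("numeric", 3)),
                stringsAsFactors = FALSE)
  need <- c("participant_id", "aces_count", "epds_total", "stai_total")
  if (!identical(names(d), need))
    stop(sprintf("expected header '%s'", paste(need, collapse = ", ")), call. = FALSE)
  chk <- function(v, lo, hi, what) {
    bad <- which(!is.na(v) & (v < lo | v > hi | v != round(v)))
    if (length(bad)) sprintf("%s outside integer %d-%d at data row(s) %s",
                             what, lo, hi, paste(bad, collapse = ", "))
  }
  problems <- c(chk(d$aces_count, 0, 10, "aces_count"),
                chk(d$epds_total, 0, 30, "epds_total"),
                chk(d$stai_total, 20, 80, "stai_total"),
                if (anyDuplicated(d$participant_id))
                  "duplicate participant_id rows")
  if (length(problems))
    stop(paste0("invalid outcomes file:\n  ",
                paste(problems, collapse = "\n  ")), call. = FALSE)
  d
}

#' Write an outcomes table
#' @param outcomes Outcomes data frame.
#' @param path Output CSV path.
#' @export
write_outcomes <- function(outcomes, path) {
  write.csv(outcomes[c("participant_id", "aces_count", "epds_total", "stai_total")],
            path, row.names = FALSE, na = "")
}

#' Run the full selection pipeline
#'
#' Orchestrates the three analysis steps: (1) multiple imputation of the
#' weekly stress panel (`m` completions) and construction of the 29
#' predictors merged with each outcome, participants missing that outcome
#' dropped; (2) one cross-validated adaptive LASSO per imputed dataset,
#' sample and outcome; (3) pooling by selection frequency.  All defaults
#' reproduce the reference settings: m = 21 imputations, 10-fold CV, ACEs
#' cutoff 4, retention at floor(m/2) = 10 of 21.
#'
#' @param panel Stress panel data frame, or path to its CSV.
#' @param outcomes Outcomes data frame, or path to its CSV.
#' @param out_dir Optional directory; when given, the imputed datasets,
#'   the report (CSV + JSON) and a provenance log (all settings and seeds)
#'   are written there.
#' @param m Number of imputations (default 21).
#' @param seed Master seed; imputation uses `seed`, model `k` uses
#'   `seed + k` for CV folds.
#' @param samples,outcome_set Which models to run (default all six).
#' @param aces_threshold,retention_threshold,policy See
#'   [run_stress_models()].
#' @param ... Further arguments to [adaptive_lasso()] (e.g. `gamma`,
#'   `nfolds`, `cv_rule`).
#' @return The `stress_selection_report`.
#' @export
run_pipeline <- function(panel, outcomes, out_dir = NULL, m = 21, seed = 1,
                         samples = c("full", "aces_high", "aces_low"),
                         outcome_set = c("depressive", "anxiety"),
                         aces_threshold = 4, retention_threshold = NULL,
                         policy = "all", ...) {
  if (is.character(panel)) panel <- read_weekly_stress(panel)
  if (is.character(outcomes)) outcomes <- read_outcomes(outcomes)

  completed <- multiply_impute(panel, m = m, base_seed = seed)
  report <- run_stress_models(completed, outcomes, samples = samples,
                              outcome_set = outcome_set,
                              aces_threshold = aces_threshold,
                              retention_threshold = retention_threshold,
                              policy = policy, seed = seed, ...)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (k in seq_len(m))
      write_weekly_stress(completed[[k]],
                          file.path(out_dir, sprintf("imputed_%02d.csv", k)))
    write.csv(report$table, file.path(out_dir, "report.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(report = report$table,
           settings = list(m = m, seed = seed,
                           threshold = report$threshold,
                           aces_threshold = aces_threshold,
                           policy = policy, samples = samples,
                           outcomes = outcome_set)),
      file.path(out_dir, "report.json"), dataframe = "rows",
      auto_unbox = TRUE, digits = NA, na = "null")
    jsonlite::write_json(
      list(m = m, seed = seed, imputation_seeds = seed + seq_len(m),
           cv_seeds = seed + seq_len(m), threshold = report$threshold,
           aces_threshold = aces_threshold, policy = policy),
      file.path(out_dir, "run_log.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}
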