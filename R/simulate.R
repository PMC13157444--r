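#' Default planted outcome effects for the synthetic cohort
#'
#' One coefficient map per ACEs group and outcome.  Postpartum outcomes are
#' generated from the *latent* person-level stress summaries as
#' `intercept + b_mean * person mean + b_sd * person SD +
#' sum_w b_week[w] * deviation_w + noise`.  The high-ACEs group carries
#' week-specific timing effects (weeks 20 and 26 for depressive symptoms,
#' week 26 for anxiety) on top of level and fluctuation effects; the
#' low-ACEs group carries a level effect only.
#'
#' @return Nested list `effects[[group]][[outcome]]` with elements
#'   `intercept`, `b_mean`, `b_sd` and a named vector `b_week`.
#' @export
default_sim_effects <- function() {
  list(
    aces_high = list(
      depressive = list(intercept = 0, b_mean = 2, b_sd = 2,
                        b_week = c("20" = 1.5, "26" = 1.5)),
      anxiety    = list(intercept = 20, b_mean = 4, b_sd = 0,
                        b_week = c("26" = 2))
    ),
    aces_low = list(
      depressive = list(intercept = 1, b_mean = 2, b_sd = 0, b_week = numeric(0)),
      anxiety    = list(intercept = 22, b_mean = 4, b_sd = 0, b_week = numeric(0))
    )
  )
}

#' Configuration for the synthetic pregnancy-stress cohort
#'
#' Weekly ordinal stress (0-6) arises by thresholding a Gaussian latent
#' process: participant `i` has latent level `mu_i ~ N(latent_mean_mu,
#' latent_mean_sd^2)` and stationary AR(1) weekly deviations with lag-1
#' correlation `ar_rho` and innovation SD `ar_sd`.  The latent value is cut
#' at `thresholds` to give the observed 0-6 score.  Default thresholds,
#' latent mean and AR scale are calibrated so that at the default settings
#' the cohort-average person mean of observed stress is about 3.01 and the
#' cohort-average within-person SD about 1.41, matching typical community
#' pregnancy cohorts.
#'
#' @param n_participants Number of participants.
#' @param week_range Inclusive integer gestational-week grid.
#' @param n_levels Number of ordinal stress levels (scores `0:(n_levels-1)`).
#' @param latent_mean_mu,latent_mean_sd Distribution of person-level latent
#'   stress means.
#' @param ar_rho Week-to-week autocorrelation of latent deviations, in `[0,1)`.
#' @param ar_sd Innovation SD of the latent AR(1) process (stationary SD is
#'   `ar_sd / sqrt(1 - ar_rho^2)`).
#' @param ar_sd_person_sigma Log-normal sigma of a person-specific
#'   volatility multiplier on the AR process (mean 1); 0 gives every
#'   participant the same volatility.  The default reproduces the
#'   between-person spread of weekly stress SDs seen in community
#'   pregnancy cohorts (person-SD spread around 0.37).
#' @param thresholds Strictly ascending cutpoints (length `n_levels - 1`)
#'   mapping latent values to ordinal scores.
#' @param p_high_aces Probability a participant is in the high-ACEs group
#'   (4 or more adverse childhood experiences).
#' @param aces_count_model Named list with probability vectors over counts
#'   0-10 for each group (`aces_high` mass on 4-10, `aces_low` on 0-3).
#' @param effects Planted outcome coefficients; see [default_sim_effects()].
#' @param outcome_noise_sd Named vector of outcome noise SDs
#'   (`depressive`, `anxiety`).
#' @param parturition_weeks Integer weeks from which each participant's
#'   delivery week is drawn uniformly.
#' @param p_intermittent_missing Probability a pre-parturition weekly value
#'   is missing (independently per cell).
#' @param p_outcome_missing Probability a participant's postpartum outcomes
#'   are missing (both instruments jointly); default reproduces roughly
#'   one-third attrition.
#' @param seed Integer seed; all generator randomness derives from it.
#'
#' @return A validated list of class `sim_config`.
#' @seealso [simulate_cohort()], [apply_missingness()]
#' @export
sim_config <- function(n_participants = 396,
                       week_range = c(15, 41),
                       n_levels = 7,
                       latent_mean_mu = 3.02,
                       latent_mean_sd = 1.25,
                       ar_rho = 0.5,
                       ar_sd = 1.45,
                       ar_sd_person_sigma = 0.25,
                       thresholds = seq(0.5, 5.5, by = 1),
                       p_high_aces = 108 / 261,
                       aces_count_model = list(
                         aces_high = c("4" = 0.35, "5" = 0.25, "6" = 0.15,
                                       "7" = 0.10, "8" = 0.07, "9" = 0.05,
                                       "10" = 0.03),
                         aces_low  = c("0" = 0.35, "1" = 0.30, "2" = 0.20,
                                       "3" = 0.15)
                       ),
                       effects = default_sim_effects(),
                       outcome_noise_sd = c(depressive = 5, anxiety = 8),
                       parturition_weeks = 37:41,
                       p_intermittent_missing = 0.15,
                       p_outcome_missing = 131 / 396,
                       seed = 1L) {
  cfg <- list(n_participants = as.integer(n_participants),
              week_range = as.integer(week_range), n_levels = as.integer(n_levels),
              latent_mean_mu = latent_mean_mu, latent_mean_sd = latent_mean_sd,
              ar_rho = ar_rho, ar_sd = ar_sd,
              ar_sd_person_sigma = ar_sd_person_sigma, thresholds = thresholds,
              p_high_aces = p_high_aces, aces_count_model = aces_count_model,
              effects = effects, outcome_noise_sd = outcome_noise_sd,
              parturition_weeks = as.integer(parturition_weeks),
              p_intermittent_missing = p_intermittent_missing,
              p_outcome_missing = p_outcome_missing, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  bad <- function(field, why) {
    stop(sprintf("invalid sim_config field '%s': %s", field, why), call. = FALSE)
  }
  if (cfg$n_participants < 1) bad("n_participants", "must be >= 1")
  if (length(cfg$week_range) != 2 || cfg$week_range[1] > cfg$week_range[2])
    bad("week_range", "lower bound must not exceed upper bound")
  if (cfg$n_levels < 2) bad("n_levels", "need at least 2 ordinal levels")
  if (length(cfg$thresholds) != cfg$n_levels - 1)
    bad("thresholds", sprintf("need %d cutpoints for %d levels",
                              cfg$n_levels - 1, cfg$n_levels))
  if (any(diff(cfg$thresholds) <= 0)) bad("thresholds", "must be strictly ascending")
  if (cfg$ar_rho < 0 || cfg$ar_rho >= 1) bad("ar_rho", "must lie in [0, 1)")
  if (cfg$ar_sd < 0) bad("ar_sd", "must be >= 0")
  if (cfg$ar_sd_person_sigma < 0) bad("ar_sd_person_sigma", "must be >= 0")
  if (cfg$latent_mean_sd < 0) bad("latent_mean_sd", "must be >= 0")
  for (f in c("p_high_aces", "p_intermittent_missing", "p_outcome_missing")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) bad(f, "probability must lie in [0, 1]")
  }
  if (any(cfg$outcome_noise_sd < 0)) bad("outcome_noise_sd", "must be >= 0")
  for (g in c("aces_high", "aces_low")) {
    pm <- cfg$aces_count_model[[g]]
    if (is.null(pm) || abs(sum(pm) - 1) > 1e-8)
      bad("aces_count_model", sprintf("probabilities for '%s' must sum to 1", g))
  }
  invisible(cfg)
}

#' Simulate a complete synthetic pregnancy-stress cohort
#'
#' Generates, for each participant, a fully observed ordinal stress
#' trajectory on the week grid, an ACEs count, and both postpartum outcome
#' totals (EPDS 0-30, STAI-state 20-80).  Outcomes are built from the
#' noise-free latent person summaries, then noise is added and totals are
#' rounded and clipped to the instrument range.  No missingness is applied
#' here; see [apply_missingness()].
#'
#' @param config A [sim_config()].
#' @return List of class `stress_cohort` with elements
#'   \describe{
#'     \item{panel}{long data frame `participant_id, gestational_week, stress`}
#'     \item{outcomes}{data frame `participant_id, aces_count, epds_total, stai_total`}
#'     \item{truth}{ground truth: latent matrix, latent person means/SDs,
#'       latent deviations, group labels, effects and config}
#'   }
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_participants
  weeks <- config$week_range[1]:config$week_range[2]
  W <- length(weeks)
  id <- sprintf("P%04d", seq_len(n))

  group <- ifelse(runif(n) < config$p_high_aces, "aces_high", "aces_low")
  aces <- integer(n)
  for (g in c("aces_high", "aces_low")) {
    idx <- which(group == g)
    pm <- config$aces_count_model[[g]]
    if (length(idx))
      aces[idx] <- sample(as.integer(names(pm)), length(idx), TRUE, prob = pm)
  }

  mu <- rnorm(n, config$latent_mean_mu, config$latent_mean_sd)
  # person-specific volatility multiplier (mean 1) times a stationary AR(1)
  sig <- config$ar_sd_person_sigma
  vol <- exp(rnorm(n, -sig^2 / 2, sig))
  e <- matrix(0, n, W)
  stat_sd <- config$ar_sd / sqrt(1 - config$ar_rho^2)
  e[, 1] <- rnorm(n, 0, stat_sd)
  for (w in seq_len(W)[-1])
    e[, w] <- config$ar_rho * e[, w - 1] + rnorm(n, 0, config$ar_sd)
  z <- mu + vol * e
  x <- matrix(findInterval(z, config$thresholds), n, W)  # ordinal 0..K-1

  pmean <- rowMeans(z)
  psd <- apply(z, 1, sd)
  dev <- z - pmean

  outc <- data.frame(participant_id = id, aces_count = aces,
                     epds_total = NA_real_, stai_total = NA_real_,
                     stringsAsFactors = FALSE)
  for (oc in c("depressive", "anxiety")) {
    y <- numeric(n)
    for (g in c("aces_high", "aces_low")) {
      idx <- which(group == g)
      if (!length(idx)) next
      ef <- config$effects[[g]][[oc]]
      yi <- ef$intercept + ef$b_mean * pmean[idx] + ef$b_sd * psd[idx]
      for (wk in names(ef$b_week)) {
        col <- match(as.integer(wk), weeks)
        if (is.na(col))
          stop(sprintf("invalid sim_config field 'effects': b_week week %s outside week_range", wk),
               call. = FALSE)
        yi <- yi + ef$b_week[[wk]] * dev[idx, col]
      }
      y[idx] <- yi
    }
    y <- y + rnorm(n, 0, config$outcome_noise_sd[[oc]])
    rng <- OUTCOME_RANGE[[oc]]
    outc[[outcome_column(oc)]] <- pmin(pmax(round(y), rng[1]), rng[2])
  }

  panel <- data.frame(
    participant_id = rep(id, each = W),
    gestational_week = rep(weeks, times = n),
    stress = as.integer(t(x)),
    stringsAsFactors = FALSE
  )

  truth <- list(latent = z, person_mean = pmean, person_sd = psd,
                deviations = dev, group = group, weeks = weeks,
                effects = config$effects, config = config)
  structure(list(panel = panel, outcomes = outc, truth = truth),
            class = "stress_cohort")
}

#' Apply parturition truncation, intermittent missingness and attrition
#'
#' Each participant draws a parturition (delivery) week; weekly values after
#' it become structurally missing.  Remaining cells are missing
#' independently with `p_intermittent_missing`, and each participant's two
#' outcome totals are jointly missing with `p_outcome_missing` (postpartum
#' attrition).  Randomness is seeded from `config$seed + 1` so the same
#' config reproduces the same masks.
#'
#' @param cohort A `stress_cohort` from [simulate_cohort()].
#' @param config The same [sim_config()] (or one with different
#'   missingness settings).
#' @return The cohort with missing cells in `panel` and `outcomes`, and
#'   `truth` extended with `parturition_week` and logical missingness masks.
#' @export
apply_missingness <- function(cohort, config) {
  stopifnot(inherits(cohort, "stress_cohort"))
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  panel <- cohort$panel
  outc <- cohort$outcomes
  id <- unique(panel$participant_id)
  n <- length(id)

  pw <- config$parturition_weeks
  part <- pw[sample.int(length(pw), n, replace = TRUE)]
  names(part) <- id
  structural <- panel$gestational_week > part[panel$participant_id]
  intermittent <- !structural &
    runif(nrow(panel)) < config$p_intermittent_missing
  panel$stress[structural | intermittent] <- NA_integer_

  out_missing <- runif(n) < config$p_outcome_missing
  outc$epds_total[out_missing] <- NA_real_
  outc$stai_total[out_missing] <- NA_real_

  cohort$panel <- panel
  cohort$outcomes <- outc
  cohort$truth$parturition_week <- part
  cohort$truth$mask_structural <- structural
  cohort$truth$mask_intermittent <- intermittent
  cohort$truth$mask_outcome <- out_missing
  cohort
}

#' Descriptive summary of a weekly stress panel
#'
#' Cohort-level mean and SD of the per-participant mean and per-participant
#' (sample) SD of observed weekly stress.
#'
#' @param panel Long stress panel data frame (or a `stress_cohort`).
#' @return List with `mean_of_means`, `sd_of_means`, `mean_of_sds`,
#'   `sd_of_sds` and `n_participants`.
#' @export
summarize_cohort <- function(panel) {
  if (inherits(panel, "stress_cohort")) panel <- panel$panel
  obs <- panel[!is.na(panel$stress), ]
  if (nrow(obs) == 0) stop("cohort has no observed stress values", call. = FALSE)
  pm <- tapply(obs$stress, obs$participant_id, mean)
  ps <- tapply(obs$stress, obs$participant_id, function(v)
    if (length(v) >= 2) sd(v) else NA_real_)
  list(mean_of_means = mean(pm), sd_of_means = sd(pm),
       mean_of_sds = mean(ps, na.rm = TRUE), sd_of_sds = sd(ps, na.rm = TRUE),
       n_participants = length(pm))
}
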