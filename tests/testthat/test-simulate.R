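zero_effects <- function(int_dep = 5, int_anx = 30) {
  e <- default_sim_effects()
  for (g in names(e)) {
    e[[g]]$depressive <- list(intercept = int_dep, b_mean = 0, b_sd = 0,
                              b_week = numeric(0))
    e[[g]]$anxiety <- list(intercept = int_anx, b_mean = 0, b_sd = 0,
                           b_week = numeric(0))
  }
  e
}

test_that("zero planted effects and zero noise give constant group outcomes", {
  cfg <- sim_config(n_participants = 40, effects = zero_effects(),
                    outcome_noise_sd = c(depressive = 0, anxiety = 0), seed = 3)
  co <- simulate_cohort(cfg)
  expect_true(all(co$outcomes$epds_total == 5))
  expect_true(all(co$outcomes$stai_total == 30))
})

test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- sim_config(n_participants = 30, seed = 11)
  a <- apply_missingness(simulate_cohort(cfg), cfg)
  b <- apply_missingness(simulate_cohort(cfg), cfg)
  expect_identical(a$panel, b$panel)
  expect_identical(a$outcomes, b$outcomes)
  expect_identical(a$truth$parturition_week, b$truth$parturition_week)
})

test_that("outcome regression on latent person mean recovers the planted slope", {
  e <- zero_effects(int_dep = 0)
  e$aces_high$depressive$b_mean <- 2
  e$aces_low$depressive$b_mean <- 2
  cfg <- sim_config(n_participants = 2000, effects = e,
                    outcome_noise_sd = c(depressive = 0, anxiety = 0), seed = 5)
  co <- simulate_cohort(cfg)
  slope <- coef(lm(co$outcomes$epds_total ~ co$truth$person_mean))[2]
  expect_lt(abs(slope - 2), 0.05)
})

test_that("ordinal values stay on the 0-6 scale and outcomes in instrument ranges", {
  cfg <- sim_config(n_participants = 200, seed = 8)
  co <- simulate_cohort(cfg)
  expect_true(all(co$panel$stress %in% 0:6))
  expect_true(all(co$outcomes$epds_total >= 0 & co$outcomes$epds_total <= 30))
  expect_true(all(co$outcomes$stai_total >= 20 & co$outcomes$stai_total <= 80))
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(sim_config(thresholds = c(1, 1, 2, 3, 4, 5)), "thresholds")
  expect_error(sim_config(ar_rho = 1), "ar_rho")
  expect_error(sim_config(p_intermittent_missing = 1.2), "p_intermittent_missing")
  expect_error(sim_config(week_range = c(30, 20)), "week_range")
})

test_that("missingness machinery matches its nominal rates", {
  # no missingness of any kind leaves the cohort untouched
  cfg0 <- sim_config(n_participants = 25, p_intermittent_missing = 0,
                     p_outcome_missing = 0, parturition_weeks = 41, seed = 2)
  co0 <- simulate_cohort(cfg0)
  expect_identical(apply_missingness(co0, cfg0)$panel, co0$panel)
  expect_identical(apply_missingness(co0, cfg0)$outcomes, co0$outcomes)

  # intermittent rate ~ 0.2 among pre-parturition cells
  cfg1 <- sim_config(n_participants = 1000, p_intermittent_missing = 0.2,
                     p_outcome_missing = 0, seed = 4)
  co1 <- apply_missingness(simulate_cohort(cfg1), cfg1)
  pre <- !co1$truth$mask_structural
  expect_lt(abs(mean(is.na(co1$panel$stress[pre])) - 0.2), 0.02)

  # attrition 131/396 leaves about 265 participants with outcomes
  cfg2 <- sim_config(n_participants = 396, seed = 6)
  co2 <- apply_missingness(simulate_cohort(cfg2), cfg2)
  expect_lt(abs(sum(!is.na(co2$outcomes$epds_total)) - 265), 30)
})

test_that("cohort summary is exact on hand-built panels", {
  p1 <- panel_from_matrix(matrix(3L, 2, 27, dimnames = list(c("a", "b"), 15:41)))
  s1 <- summarize_cohort(p1)
  expect_equal(s1$mean_of_means, 3)
  expect_equal(s1$mean_of_sds, 0)

  v <- rbind(a = rep(2L, 27), b = rep(4L, 27))
  colnames(v) <- 15:41
  expect_equal(summarize_cohort(panel_from_matrix(v))$mean_of_means, 3)

  expect_error(summarize_cohort(data.frame(participant_id = "a",
                                           gestational_week = 15L,
                                           stress = NA_integer_)),
               "no observed")
})

test_that("default calibration reproduces the reference cohort descriptives", {
  s <- summarize_cohort(simulate_cohort(sim_config(n_participants = 2000, seed = 7)))
  expect_lt(abs(s$mean_of_means - 3.01), 0.15)
  expect_lt(abs(s$mean_of_sds - 1.41), 0.15)
})

test_that("a larger level effect strictly strengthens the mean-outcome correlation", {
  cors <- vapply(c(0.5, 1.5, 3), function(b) {
    e <- zero_effects(int_dep = 0)
    e$aces_high$depressive$b_mean <- b
    e$aces_low$depressive$b_mean <- b
    cfg <- sim_config(n_participants = 1500, effects = e,
                      outcome_noise_sd = c(depressive = 3, anxiety = 3), seed = 9)
    co <- simulate_cohort(cfg)
    cor(co$truth$person_mean, co$outcomes$epds_total)
  }, numeric(1))
  expect_true(all(diff(cors) > 0))
})
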