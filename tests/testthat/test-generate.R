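test_that("arm sizes match the specification and generation is deterministic", {
  cfg <- default_config(seed = 7, n = c(170L, 170L, 170L), missingness = FALSE)
  co1 <- generate_cohort(cfg)
  co2 <- generate_cohort(cfg)
  expect_equal(nrow(co1$baseline), 510L)
  expect_equal(unname(table(co1$baseline$arm)), array(c(170L, 170L, 170L)))
  expect_identical(co1$baseline, co2$baseline)
  expect_identical(co1$panel, co2$panel)
  # a different seed changes the draw
  co3 <- generate_cohort(default_config(seed = 8, n = c(170L, 170L, 170L),
                                        missingness = FALSE))
  expect_false(identical(co1$baseline$absence_days, co3$baseline$absence_days))
})

test_that("generated records satisfy the schema invariants", {
  co <- tiny_cohort(n = 150, seed = 11)
  b <- co$baseline
  p <- co$panel
  expect_true(all(p$absence_fraction >= 0 & p$absence_fraction <= 1))
  expect_equal(nrow(p), nrow(b) * 12L)
  msk <- as.matrix(b[, paste0("mskhq_", c(0, 3, 6, 9, 12))])
  expect_true(all(msk >= 0 & msk <= 56))
  expect_true(all(b$utility_baseline >= -0.594 & b$utility_baseline <= 1))
  expect_true(all(b$utility_12m >= -0.594 & b$utility_12m <= 1))
  costs <- as.matrix(b[, c("cost_intervention", "cost_healthcare_primary",
                           "cost_healthcare_secondary", "cost_absenteeism",
                           "cost_unpaid")])
  expect_true(all(costs >= 0))
  # conservation: total equals the component sum exactly
  expect_equal(b$cost_total, rowSums(costs), tolerance = 1e-12)
  # cost coherence: absenteeism = days x sex-stratified daily wage, exactly
  wage <- co$config$wage_table
  expect_equal(b$cost_absenteeism, b$absence_days * unname(wage[b$sex]))
  # default coupling: benefit received whenever any absence is recorded
  expect_true(all(p$benefit_received == (p$absence_fraction > 0)))
})

test_that("pre-RTW absence stays at or above the detector threshold", {
  co <- tiny_cohort(n = 120, seed = 13)
  rtw <- sustained_rtw(co)
  p <- co$panel
  for (i in sample(rtw$id, 25)) {
    t <- rtw$time[rtw$id == i]
    pre <- p$absence_fraction[p$id == i & p$month < t]
    if (rtw$event[rtw$id == i] == 1 && t > 1)
      expect_true(all(pre >= 0.5))
  }
})

test_that("the generator recovers the configured absence-day shift", {
  cfg <- two_arm_config(n = 5000, seed = 1, shift = -17)
  b <- generate_cohort(cfg)$baseline
  diff <- mean(b$absence_days[b$arm == "B"]) - mean(b$absence_days[b$arm == "A"])
  expect_lt(abs(diff - (-17)), 2)
})

test_that("missingness overlay matches configured rates and is MAR", {
  # zero rates leave the cohort untouched
  co <- tiny_cohort(n = 80, seed = 5)
  co0 <- impose_missingness(co, cohort_config(co$config$arms, seed = 5,
                                              missingness_rates = list()))
  expect_identical(co0$baseline, co$baseline)

  # rate 0.5 on n = 10 000 lands within tight binomial error
  cfg <- cohort_config(list(arm_spec("A", 10000)), seed = 2,
                       missingness_rates = list(workability = 0.5))
  co <- impose_missingness(generate_cohort(cfg))
  rate <- mean(is.na(co$baseline$workability))
  expect_gte(rate, 0.49); expect_lte(rate, 0.51)

  # rate 0.04 on n = 509: about 20 absent values (binomial 95% range 12..30)
  cfg <- default_config(seed = 3, missingness = FALSE)
  cfg$missingness_rates <- list(mskhq_0 = 0.04)
  co <- impose_missingness(generate_cohort(cfg), cfg)
  n_miss <- sum(is.na(co$baseline$mskhq_0))
  expect_gte(n_miss, qbinom(0.025, 509, 0.04))
  expect_lte(n_miss, qbinom(0.975, 509, 0.04))

  # rates at or above 1 are rejected, unknown variables are rejected
  expect_error(cohort_config(list(arm_spec("A", 5)),
                             missingness_rates = list(workability = 1)),
               "missingness")
  co <- tiny_cohort(n = 20, seed = 4)
  co$config$missingness_rates <- list(nonexistent = 0.1)
  expect_error(impose_missingness(co), "unknown variable")
})

test_that("logistic benefit mode recovers the configured odds ratio", {
  cfg <- two_arm_config(n = 5000, seed = 9, or = 0.73, benefit_mode = "logistic")
  co <- generate_cohort(cfg)
  fit <- monthly_benefit_model(co)
  expect_lt(abs(fit$estimate - 0.73), 0.05)
  expect_true(fit$lcl < 0.73 && 0.73 < fit$ucl)
})
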