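test_that("micro-costing amortizes one-off costs and applies overhead", {
  # pure delivery cost: EUR 53 per participant regardless of n
  expect_equal(micro_cost_intervention(session_hours = 1,
                                       sessions_per_participant = 1,
                                       delivery_rate = 53,
                                       n_participants = 169), 53)
  # training EUR 1000 over 100 participants + EUR 40 delivery, no overhead
  expect_equal(micro_cost_intervention(training_hours = 10, training_rate = 100,
                                       session_hours = 1,
                                       sessions_per_participant = 1,
                                       delivery_rate = 40,
                                       n_participants = 100), 50)
  # doubling n halves the amortized component
  c1 <- micro_cost_intervention(training_hours = 10, training_rate = 100,
                                n_participants = 100)
  c2 <- micro_cost_intervention(training_hours = 10, training_rate = 100,
                                n_participants = 200)
  expect_equal(c1, 2 * c2)
  # overhead scales the total
  expect_equal(micro_cost_intervention(session_hours = 2,
                                       sessions_per_participant = 1,
                                       delivery_rate = 50, overhead = 0.2,
                                       n_participants = 10), 120)
  expect_error(micro_cost_intervention(n_participants = 0), "n_participants")
  expect_error(micro_cost_intervention(training_hours = -1, n_participants = 5),
               "non-negative")
})

test_that("valuation operations are linear and wage-stratified", {
  wt <- c(female = 210, male = 240)
  expect_equal(value_absenteeism(0, "female", wt), 0)
  expect_equal(value_absenteeism(100, "male", wt), 24000)
  expect_equal(value_absenteeism(c(10, 10), c("female", "male"), wt),
               c(2100, 2400))
  expect_error(value_absenteeism(10, "other", wt), "other")
  expect_error(value_absenteeism(-1, "male", wt), "negative")

  expect_equal(value_unpaid_productivity(0, 15), 0)
  expect_equal(value_unpaid_productivity(100, 15), 1500)
  expect_equal(value_unpaid_productivity(100, 0), 0)
  expect_error(value_unpaid_productivity(-1, 15), "negative")

  # linearity: value(a + b) = value(a) + value(b)
  expect_equal(value_absenteeism(7 + 5, "male", wt),
               value_absenteeism(7, "male", wt) + value_absenteeism(5, "male", wt))
})

test_that("currency conversion is a pure scaling that commutes with sums", {
  expect_equal(convert_currency(1000), 1000)
  expect_equal(convert_currency(1000, exchange_rate = 0.098), 98)
  a <- c(120.5, 980, 3)
  expect_equal(convert_currency(sum(a), 1.04, 0.098),
               sum(convert_currency(a, 1.04, 0.098)))
  expect_error(convert_currency(10, exchange_rate = 0), "exchange_rate")
})

test_that("QALY construction follows the declared method", {
  expect_equal(compute_qaly(c(1, 1), c(0, 12)), 1)
  expect_equal(compute_qaly(c(0.6, 0.8), c(0, 12), method = "auc-linear"), 0.7)
  expect_equal(compute_qaly(0.68, 12, method = "single-point"), 0.68)
  # six-month horizon scales the single-point construction
  expect_equal(compute_qaly(0.5, 6, followup_months = 6), 0.25)
  # trapezoid over three timepoints
  expect_equal(compute_qaly(c(0.5, 0.7, 0.9), c(0, 6, 12), "auc-linear"),
               (6 * 0.6 + 6 * 0.8) / 12)
  expect_error(compute_qaly(NA_real_), "utility")
})

test_that("cost table differences are linear in components", {
  b <- tiny_cohort(n = 100, seed = 71)$baseline
  tab <- cost_difference_table(b, B = 200, seed = 1)
  for (cmp in unique(tab$comparison)) {
    tt <- tab[tab$comparison == cmp, ]
    total <- tt[tt$component == "cost_total", ]
    comps <- tt[tt$component != "cost_total", ]
    # component mean differences sum exactly to the total difference
    expect_equal(sum(comps$diff_unadj), total$diff_unadj, tolerance = 1e-9)
    # arm means agree with direct averages
    expect_equal(total$mean_ref,
                 mean(b$cost_total[b$arm == levels(b$arm)[1]]))
  }
  # missing values are rejected with a pointer to imputation
  b2 <- b; b2$cost_unpaid[3] <- NA
  expect_error(cost_difference_table(b2), "impute")
})

test_that("identical arms give cost differences compatible with zero", {
  cfg <- two_arm_config(n = 400, seed = 73)
  b <- generate_cohort(cfg)$baseline
  tab <- cost_difference_table(b, B = 400, seed = 2)
  tot <- tab[tab$component == "cost_total", ]
  expect_true(tot$lcl_unadj < 0 && 0 < tot$ucl_unadj)
})
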