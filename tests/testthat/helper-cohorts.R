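# Small cohort configurations reused across tests.

two_arm_config <- function(n = 200, seed = 1, hr = 1, shift = 0, or = 1,
                           benefit_mode = "coupled", ...) {
  cohort_config(
    arms = list(arm_spec("A", n),
                arm_spec("B", n, absence_day_shift = shift,
                         rtw_hazard_ratio = hr, benefit_odds_ratio = or)),
    seed = seed, benefit_mode = benefit_mode, missingness_rates = list(), ...)
}

tiny_cohort <- function(n = 60, seed = 3) {
  generate_cohort(default_config(seed = seed, n = rep(n, 3), missingness = FALSE))
}

# hand-built survival outcome table
surv_df <- function(time, event) data.frame(id = seq_along(time), time = time,
                                            event = event)
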