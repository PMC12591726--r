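#' Generate a synthetic three-arm return-to-work cohort
#'
#' Draws a participant-level trial dataset with the structure the downstream
#' analyses assume: baseline covariates, a 12-month panel of monthly absence
#' fractions and benefit-receipt flags built around a single sustained-RTW
#' transition (with optional one-month relapses after the confirmation
#' window), repeated musculoskeletal-health scores, baseline and 12-month
#' utilities, and per-participant cost components. Absenteeism cost is the
#' registry absence-day count times the sex-specific daily wage, exactly.
#'
#' The sustained-RTW month is drawn per participant from the discrete-time
#' proportional-hazards model `S_arm(m) = S_0(m)^HR`, where `S_0` is the
#' survival curve implied by `config$baseline_hazard` and `HR` the arm's
#' `rtw_hazard_ratio`, so a Cox model on the detected RTW times recovers the
#' generator hazard ratios. Before RTW the monthly absence fraction stays at
#' or above 0.5 (the trial population is on >= 50 percent sick leave),
#' decaying from its starting level towards 0.5; after RTW it is zero except
#' for relapse months.
#'
#' @param config A [cohort_config()].
#' @return An object of class `trial_cohort`: a list with `baseline` (one row
#'   per participant), `panel` (long person-month table: `id`, `month`,
#'   `absence_fraction`, `benefit_received`) and the `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(stage_seed(config$seed, "simulate"))
  months <- config$months
  S0 <- cumprod(1 - config$baseline_hazard)

  base_list <- vector("list", length(config$arms))
  panel_list <- vector("list", length(config$arms))
  id0 <- 0L
  for (k in seq_along(config$arms)) {
    a <- config$arms[[k]]
    n <- a$n
    id <- id0 + seq_len(n)
    id0 <- id0 + n

    # --- baseline covariates --------------------------------------------
    age <- pmin(pmax(round(stats::rnorm(n, 48, 10)), 18), 67)
    sex <- ifelse(stats::runif(n) < 0.57, "female", "male")
    education <- ifelse(stats::runif(n) < 0.37, "high", "low")
    workability <- pmin(pmax(round(stats::rnorm(n, 3, 2.6)), 0), 10)
    physical_activity <- ifelse(stats::runif(n) < 0.39, "high", "low")
    employer_followup <- stats::runif(n) < 0.75
    risk_group <- ifelse(stats::runif(n) < config$risk_group_proportion,
                         "high", "medium_low")
    prior_absence_days <- pmin(round(stats::rlnorm(n, log(36), 0.85)), 220)
    baseline_absence_days <- pmin(round(stats::rlnorm(n, log(51), 0.8)), 372)

    # --- sustained-RTW month under discrete-time PH ---------------------
    S_arm <- S0^a$rtw_hazard_ratio
    # P(event in month m) = S_arm[m-1] - S_arm[m]; censored with prob S_arm[M]
    pm <- c(-diff(c(1, S_arm)), S_arm[months])
    rtw_month <- apply(stats::rmultinom(n, 1L, pm), 2L, which.max) # months+1 = censored
    full <- stats::runif(n) < config$prob_full_absence
    f0 <- ifelse(full, 1,
                 stats::runif(n, config$partial_absence_range[1],
                              config$partial_absence_range[2]))

    frac <- matrix(0, nrow = n, ncol = months)
    for (m in seq_len(months)) {
      pre <- m < rtw_month
      frac[pre, m] <- 0.5 + (f0[pre] - 0.5) * config$absence_decay^(m - 1)
    }
    # one-month relapses, only after the 4-month confirmation window so the
    # detected sustained-RTW month equals the drawn one
    if (config$relapse_prob > 0) {
      for (m in seq_len(months)) {
        can_relapse <- (rtw_month + 3L) < m
        hit <- can_relapse & stats::runif(n) < config$relapse_prob
        frac[hit, m] <- 1
      }
    }

    # --- benefit receipt -------------------------------------------------
    if (config$benefit_mode == "coupled") {
      ben <- frac > 0
    } else {
      lp <- stats::qlogis(config$benefit_baseline_prob) + log(a$benefit_odds_ratio)
      p <- stats::plogis(lp)
      ben <- matrix(stats::runif(n * months) <
                      matrix(p, nrow = n, ncol = months, byrow = TRUE),
                    nrow = n)
    }

    # --- registry absence days (12-month outcome) ------------------------
    panel_days <- rowSums(frac) * config$workdays_per_month
    absence_days <- pmax(0, round(panel_days + a$absence_day_shift +
                                    stats::rnorm(n, 0, config$day_noise_sd)))

    # --- MSK-HQ trajectory ------------------------------------------------
    mm <- config$mskhq_model
    msk0 <- pmin(pmax(round(stats::rnorm(n, mm$mean_baseline, mm$sd_baseline)), 0), 56)
    bint <- stats::rnorm(n, 0, mm$sd_intercept)
    qtr <- c(3, 6, 9, 12)
    msk <- matrix(NA_real_, n, 4)
    for (j in 1:4) {
      mu <- msk0 + mm$recovery[j] + a$mskhq_shift_12m * qtr[j] / 12 + bint +
        stats::rnorm(n, 0, mm$sd_residual)
      msk[, j] <- pmin(pmax(round(mu), 0), 56)
    }

    # --- utilities ---------------------------------------------------------
    um <- config$utility_model
    mu12 <- if (is.null(a$utility_mean_12m)) um$mean_12m else a$utility_mean_12m
    utility_baseline <- rtruncnorm(n, um$mean_baseline, um$sd_baseline, um$floor, 1)
    utility_12m <- rtruncnorm(n, mu12, um$sd_12m, um$floor, 1)

    # --- cost components ----------------------------------------------------
    cd <- config$cost_distributions
    hc1 <- rzigamma(n, cd$healthcare_primary, a$healthcare_cost_scale)
    hc2 <- rzigamma(n, cd$healthcare_secondary, a$healthcare_cost_scale)
    unpaid_hours <- rzigamma(n, cd$unpaid_hours, a$unpaid_cost_scale)
    cost_intervention <- if (a$intervention_unit_cost > 0) {
      sdv <- cd$intervention_sd
      shp <- (a$intervention_unit_cost / sdv)^2
      stats::rgamma(n, shape = shp, rate = shp / a$intervention_unit_cost)
    } else rep(0, n)
    cost_absenteeism <- value_absenteeism(absence_days, sex, config$wage_table)
    cost_unpaid <- value_unpaid_productivity(unpaid_hours, config$shadow_price)

    base_list[[k]] <- data.frame(
      id = id, arm = a$label, age = age, sex = sex, education = education,
      workability = workability, physical_activity = physical_activity,
      employer_followup = employer_followup, risk_group = risk_group,
      prior_absence_days = prior_absence_days,
      baseline_absence_days = baseline_absence_days,
      mskhq_0 = msk0, mskhq_3 = msk[, 1], mskhq_6 = msk[, 2],
      mskhq_9 = msk[, 3], mskhq_12 = msk[, 4],
      utility_baseline = utility_baseline, utility_12m = utility_12m,
      absence_days = absence_days,
      cost_intervention = cost_intervention,
      cost_healthcare_primary = hc1,
      cost_healthcare_secondary = hc2,
      unpaid_hours = unpaid_hours,
      cost_absenteeism = cost_absenteeism,
      cost_unpaid = cost_unpaid,
      stringsAsFactors = FALSE)

    panel_list[[k]] <- data.frame(
      id = rep(id, each = months),
      month = rep(seq_len(months), times = n),
      absence_fraction = as.vector(t(frac)),
      benefit_received = as.vector(t(ben)))
  }

  baseline <- do.call(rbind, base_list)
  baseline$cost_total <- with(baseline, cost_intervention +
                                cost_healthcare_primary + cost_healthcare_secondary +
                                cost_absenteeism + cost_unpaid)
  baseline$arm <- factor(baseline$arm,
                         levels = vapply(config$arms, `[[`, character(1), "label"))
  rownames(baseline) <- NULL
  structure(list(baseline = baseline,
                 panel = do.call(rbind, panel_list),
                 config = config),
            class = "trial_cohort")
}

#' @export
print.trial_cohort <- function(x, ...) {
  cat("Synthetic trial cohort:", nrow(x$baseline), "participants,",
      x$config$months, "months of follow-up\n")
  print(table(x$baseline$arm))
  invisible(x)
}

# truncated normal via inverse-CDF (vectorised, exact)
rtruncnorm <- function(n, mean, sd, lower, upper) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(pl + stats::runif(n) * (pu - pl), mean, sd)
}

# zero-inflated gamma; 'scale_mult' rescales the component mean
rzigamma <- function(n, d, scale_mult = 1) {
  mean_pos <- d$mean * scale_mult / (1 - d$zero_prob)
  x <- stats::rgamma(n, shape = d$shape, rate = d$shape / mean_pos)
  x[stats::runif(n) < d$zero_prob] <- 0
  x
}

#' Overlay missing-at-random values on a generated cohort
#'
#' Replaces a configured proportion of values in selected baseline variables
#' by `NA`. The mechanism is missing at random: the missingness probability
#' for each participant depends only on fully observed covariates (age and
#' sex, both centred so the marginal rate matches the configured one), never
#' on the value being removed.
#'
#' @param cohort A `trial_cohort`.
#' @param config Optional [cohort_config()]; defaults to `cohort$config`.
#'   Rates are taken from `config$missingness_rates`, a named list keyed by
#'   baseline column name.
#' @param seed Optional seed; defaults to the missingness-stage child seed.
#' @return The cohort with `NA`s inserted in the baseline table.
#' @export
impose_missingness <- function(cohort, config = cohort$config, seed = NULL) {
  stopifnot(inherits(cohort, "trial_cohort"))
  rates <- config$missingness_rates
  if (!length(rates)) return(cohort)
  r <- unlist(rates)
  if (any(r >= 1) || any(r < 0))
    stop("impose_missingness: rates must lie in [0, 1)", call. = FALSE)
  if (is.null(seed)) seed <- stage_seed(config$seed, "missingness")
  set.seed(seed)
  b <- cohort$baseline
  z_age <- as.numeric(scale(b$age))
  fem <- b$sex == "female"
  z_sex <- fem - mean(fem)
  for (v in names(rates)) {
    if (!v %in% names(b))
      stop("impose_missingness: unknown variable '", v, "'", call. = FALSE)
    rate <- rates[[v]]
    if (rate == 0) next
    p <- stats::plogis(stats::qlogis(rate) + 0.3 * z_age + 0.4 * z_sex)
    b[[v]][stats::runif(nrow(b)) < p] <- NA
  }
  cohort$baseline <- b
  cohort
}
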