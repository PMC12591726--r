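#' Specify one trial arm
#'
#' An arm specification bundles the generator-level parameters that encode an
#' arm's contrast against usual case management (UC): the mean shift in annual
#' sickness-absence days, the multiplicative monthly hazard of sustained
#' return to work (RTW), the odds of receiving wage-replacement benefits in a
#' given month, the per-participant intervention cost, and multipliers on the
#' healthcare and unpaid-productivity cost distributions.
#'
#' @param label Arm name, e.g. `"UC"`, `"UC+MI"`, `"UC+SVAI"`.
#' @param n Number of participants (>= 1).
#' @param absence_day_shift Additive mean shift, in days per year, of the
#'   registry sickness-absence day count relative to what the monthly
#'   trajectory implies. Negative values mean fewer absence days.
#' @param rtw_hazard_ratio Multiplicative hazard of sustained RTW versus the
#'   baseline (UC) monthly hazard, applied on the discrete-time proportional
#'   hazards scale `S_arm(m) = S_0(m)^HR`. Must be positive.
#' @param benefit_odds_ratio Odds ratio of monthly benefit receipt versus UC,
#'   used when `benefit_mode = "logistic"`. Must be positive.
#' @param intervention_unit_cost Mean intervention cost per participant (EUR).
#' @param healthcare_cost_scale Multiplier on the mean of the healthcare cost
#'   distributions (primary and secondary).
#' @param unpaid_cost_scale Multiplier on the mean of the unpaid-productivity
#'   hours distribution; defaults to `healthcare_cost_scale`.
#' @param mskhq_shift_12m Additive shift, in MSK-HQ points at 12 months, of
#'   the musculoskeletal-health trajectory versus UC (ramped linearly over
#'   follow-up).
#' @param utility_mean_12m Optional arm-specific mean 12-month utility; when
#'   `NULL` the cohort-level utility model mean is used.
#'
#' @return An object of class `arm_spec`.
#' @export
arm_spec <- function(label, n,
                     absence_day_shift = 0,
                     rtw_hazard_ratio = 1,
                     benefit_odds_ratio = 1,
                     intervention_unit_cost = 0,
                     healthcare_cost_scale = 1,
                     unpaid_cost_scale = healthcare_cost_scale,
                     mskhq_shift_12m = 0,
                     utility_mean_12m = NULL) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label))
    stop("arm_spec: 'label' must be a non-empty string", call. = FALSE)
  n <- as.integer(n)
  if (is.na(n) || n < 1L)
    stop("arm_spec: 'n' must be an integer >= 1", call. = FALSE)
  if (!is.finite(rtw_hazard_ratio) || rtw_hazard_ratio <= 0)
    stop("arm_spec: 'rtw_hazard_ratio' must be > 0", call. = FALSE)
  if (!is.finite(benefit_odds_ratio) || benefit_odds_ratio <= 0)
    stop("arm_spec: 'benefit_odds_ratio' must be > 0", call. = FALSE)
  if (!is.finite(intervention_unit_cost) || intervention_unit_cost < 0)
    stop("arm_spec: 'intervention_unit_cost' must be >= 0", call. = FALSE)
  if (!is.finite(healthcare_cost_scale) || healthcare_cost_scale <= 0)
    stop("arm_spec: 'healthcare_cost_scale' must be > 0", call. = FALSE)
  structure(
    list(label = label, n = n,
         absence_day_shift = absence_day_shift,
         rtw_hazard_ratio = rtw_hazard_ratio,
         benefit_odds_ratio = benefit_odds_ratio,
         intervention_unit_cost = intervention_unit_cost,
         healthcare_cost_scale = healthcare_cost_scale,
         unpaid_cost_scale = unpaid_cost_scale,
         mskhq_shift_12m = mskhq_shift_12m,
         utility_mean_12m = utility_mean_12m),
    class = "arm_spec")
}

#' Cohort generator configuration
#'
#' Collects everything the synthetic-trial generator needs: the arm
#' specifications, the master seed, the length of follow-up, the baseline
#' monthly hazard of sustained RTW, the shape of the pre-RTW absence
#' trajectory, cost-component distributions, the utility model,
#' missingness rates for the missing-at-random overlay, and the wage and
#' shadow-price tables used to value productivity losses.
#'
#' @param arms List of [arm_spec()] objects (reference arm first).
#' @param seed Master integer seed; per-stage child seeds are derived from it
#'   by fixed offsets (see [stage_seed()]).
#' @param months Follow-up length in months (default 12).
#' @param baseline_hazard Either a single monthly probability of sustained RTW
#'   for the reference arm, or a vector of length `months` of month-specific
#'   discrete hazards.
#' @param relapse_prob Monthly probability of a one-month absence relapse
#'   after the sustained-RTW confirmation window.
#' @param prob_full_absence Probability that a participant is on a 100 percent
#'   (rather than partial, 50-100 percent) sick leave before RTW.
#' @param partial_absence_range Range of the pre-RTW absence fraction for
#'   participants on partial sick leave.
#' @param absence_decay Monthly multiplicative decay of the pre-RTW absence
#'   fraction towards the 0.5 floor (graded RTW).
#' @param workdays_per_month Compensated workdays per month used to convert
#'   monthly absence fractions into annual absence days.
#' @param day_noise_sd SD of the registry-versus-panel discrepancy added to
#'   the absence-day count (days).
#' @param benefit_mode `"coupled"` (benefit received whenever any absence is
#'   recorded in the month - the default definition "any benefit day in the
#'   month") or `"logistic"` (person-month benefit drawn from a month-baseline
#'   logit shifted by the arm's log odds ratio).
#' @param benefit_baseline_prob Monthly benefit-receipt probabilities for the
#'   reference arm under `benefit_mode = "logistic"`; defaults to the survival
#'   curve implied by `baseline_hazard`.
#' @param missingness_rates Named list of per-variable missingness
#'   proportions in `[0, 1)` for [impose_missingness()].
#' @param cost_distributions Named list with elements `healthcare_primary`,
#'   `healthcare_secondary` (EUR) and `unpaid_hours` (hours), each a list with
#'   `mean`, `shape` (gamma shape) and `zero_prob` (point mass at zero);
#'   plus `intervention_sd` (EUR).
#' @param utility_model List with `mean_baseline`, `sd_baseline`, `mean_12m`,
#'   `sd_12m`, and the EQ-5D-5L floor `floor` (default -0.594); utilities are
#'   drawn truncated-normal on `[floor, 1]`.
#' @param mskhq_model List with baseline mean/sd, the population recovery (in
#'   points) at each follow-up quarter, the random-intercept SD and the
#'   residual SD.
#' @param wage_table Named daily wages (EUR per workday) by sex, used to value
#'   absenteeism.
#' @param shadow_price EUR per hour of unpaid work lost.
#' @param risk_group_proportion Fraction labelled high-risk for long-term
#'   sickness absence.
#'
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(arms, seed = 1L, months = 12L,
                          baseline_hazard = NULL,
                          relapse_prob = 0.05,
                          prob_full_absence = 0.6,
                          partial_absence_range = c(0.5, 0.9),
                          absence_decay = 0.45,
                          workdays_per_month = 20,
                          day_noise_sd = 15,
                          benefit_mode = c("coupled", "logistic"),
                          benefit_baseline_prob = NULL,
                          missingness_rates = list(),
                          cost_distributions = default_cost_distributions(),
                          utility_model = default_utility_model(),
                          mskhq_model = default_mskhq_model(),
                          wage_table = c(female = 210, male = 240),
                          shadow_price = 15,
                          risk_group_proportion = 0.35) {
  if (inherits(arms, "arm_spec")) arms <- list(arms)
  if (!length(arms) || !all(vapply(arms, inherits, logical(1), "arm_spec")))
    stop("cohort_config: 'arms' must be a list of arm_spec objects", call. = FALSE)
  months <- as.integer(months)
  if (is.na(months) || months < 1L)
    stop("cohort_config: 'months' must be >= 1", call. = FALSE)
  if (is.null(baseline_hazard)) baseline_hazard <- default_monthly_hazard(months)
  if (length(baseline_hazard) == 1L) baseline_hazard <- rep(baseline_hazard, months)
  if (length(baseline_hazard) != months)
    stop("cohort_config: 'baseline_hazard' must have length 1 or 'months'", call. = FALSE)
  if (any(!is.finite(baseline_hazard)) || any(baseline_hazard < 0) || any(baseline_hazard >= 1))
    stop("cohort_config: 'baseline_hazard' entries must lie in [0, 1)", call. = FALSE)
  rates <- unlist(missingness_rates)
  if (length(rates) && (any(rates < 0) || any(rates >= 1)))
    stop("cohort_config: 'missingness_rates' must lie in [0, 1)", call. = FALSE)
  if (risk_group_proportion < 0 || risk_group_proportion > 1)
    stop("cohort_config: 'risk_group_proportion' must lie in [0, 1]", call. = FALSE)
  validate_cost_distributions(cost_distributions)
  benefit_mode <- match.arg(benefit_mode)
  if (is.null(benefit_baseline_prob))
    benefit_baseline_prob <- pmin(pmax(cumprod(1 - baseline_hazard), 0.02), 0.98)
  if (length(benefit_baseline_prob) != months)
    stop("cohort_config: 'benefit_baseline_prob' must have length 'months'", call. = FALSE)
  labels <- vapply(arms, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    stop("cohort_config: duplicated arm labels", call. = FALSE)
  structure(
    list(arms = arms, seed = as.integer(seed), months = months,
         baseline_hazard = baseline_hazard,
         relapse_prob = relapse_prob,
         prob_full_absence = prob_full_absence,
         partial_absence_range = partial_absence_range,
         absence_decay = absence_decay,
         workdays_per_month = workdays_per_month,
         day_noise_sd = day_noise_sd,
         benefit_mode = benefit_mode,
         benefit_baseline_prob = benefit_baseline_prob,
         missingness_rates = missingness_rates,
         cost_distributions = cost_distributions,
         utility_model = utility_model,
         mskhq_model = mskhq_model,
         wage_table = wage_table,
         shadow_price = shadow_price,
         risk_group_proportion = risk_group_proportion),
    class = "cohort_config")
}

validate_cost_distributions <- function(cd) {
  for (nm in c("healthcare_primary", "healthcare_secondary", "unpaid_hours")) {
    d <- cd[[nm]]
    if (is.null(d) || !all(c("mean", "shape", "zero_prob") %in% names(d)))
      stop(sprintf("cohort_config: cost_distributions$%s must supply mean, shape, zero_prob", nm),
           call. = FALSE)
    if (d$mean < 0 || d$shape <= 0 || d$zero_prob < 0 || d$zero_prob >= 1)
      stop(sprintf("cohort_config: invalid parameters in cost_distributions$%s", nm),
           call. = FALSE)
  }
  invisible(cd)
}

#' @rdname cohort_config
#' @export
default_cost_distributions <- function() {
  list(
    healthcare_primary   = list(mean = 1046, shape = 1.0, zero_prob = 0.10),
    healthcare_secondary = list(mean = 141,  shape = 0.8, zero_prob = 0.70),
    unpaid_hours         = list(mean = 186,  shape = 0.35, zero_prob = 0.50),
    intervention_sd      = 35
  )
}

#' @rdname cohort_config
#' @export
default_utility_model <- function() {
  list(mean_baseline = 0.58, sd_baseline = 0.20,
       mean_12m = 0.68, sd_12m = 0.15, floor = -0.594)
}

#' @rdname cohort_config
#' @export
default_mskhq_model <- function() {
  list(mean_baseline = 27, sd_baseline = 8,
       recovery = c(5, 7, 7.5, 7.5),   # mean gain at months 3, 6, 9, 12
       sd_intercept = 4, sd_residual = 5)
}

#' Month-specific baseline hazard of sustained RTW
#'
#' Discrete monthly hazards for the reference arm, back-derived from a
#' 12-month survival curve for "no sustained RTW" typical of workers on sick
#' leave for musculoskeletal disorders (about 43 percent reach sustained RTW
#' by month 6 and 81 percent by month 12). For follow-up other than 12 months
#' the hazard sequence is truncated or recycled at its terminal value.
#'
#' @param months Follow-up length.
#' @return Numeric vector of length `months` of per-month hazards.
#' @export
default_monthly_hazard <- function(months = 12L) {
  surv <- c(0.98, 0.91, 0.82, 0.70, 0.61, 0.57, 0.54, 0.50, 0.38, 0.29, 0.23, 0.19)
  haz <- 1 - surv / c(1, surv[-length(surv)])
  if (months <= length(haz)) haz[seq_len(months)]
  else c(haz, rep(haz[length(haz)], months - length(haz)))
}

#' Paper-calibrated three-arm default configuration
#'
#' The shipped study conditions: a usual-case-management (UC) reference arm of
#' 171 participants and two intervention arms (UC+MI, UC+SVAI) of 169 each,
#' with sustained-RTW hazard ratios 1.17 and 1.27, total mean absence-day
#' reductions of about 15.6 and 17.6 days, monthly benefit odds ratios 0.73
#' and 0.74, micro-costed intervention unit costs of EUR 53 and EUR 78, and
#' healthcare / unpaid-productivity cost distributions scaled below UC.
#'
#' The absence-day shift entered for each intervention arm is the residual
#' additive shift left after the day reduction already implied by its RTW
#' hazard ratio, so that the total generator-level mean contrast equals the
#' target day difference (see the methods vignette for the calibration).
#'
#' @param seed Master seed.
#' @param n Per-arm sample sizes, length 3 (UC, UC+MI, UC+SVAI).
#' @param missingness Whether to include the default baseline-covariate
#'   missingness rates (workability 0.006, physical activity 0.002,
#'   musculoskeletal health 0.04, employer follow-up 0.014).
#' @return A [cohort_config()].
#' @export
default_config <- function(seed = 1L, n = c(171L, 169L, 169L), missingness = TRUE) {
  stopifnot(length(n) == 3L)
  arms <- list(
    arm_spec("UC",      n[1]),
    arm_spec("UC+MI",   n[2],
             absence_day_shift = -11.2,
             rtw_hazard_ratio = 1.17,
             benefit_odds_ratio = 0.73,
             intervention_unit_cost = 53,
             healthcare_cost_scale = 0.96,
             unpaid_cost_scale = 0.65,
             mskhq_shift_12m = 2,
             utility_mean_12m = 0.71),
    arm_spec("UC+SVAI", n[3],
             absence_day_shift = -10.5,
             rtw_hazard_ratio = 1.27,
             benefit_odds_ratio = 0.74,
             intervention_unit_cost = 78,
             healthcare_cost_scale = 0.88,
             unpaid_cost_scale = 0.63,
             mskhq_shift_12m = 3,
             utility_mean_12m = 0.69))
  rates <- if (missingness)
    list(workability = 0.006, physical_activity = 0.002,
         mskhq_0 = 0.04, employer_followup = 0.014)
  else list()
  cohort_config(arms = arms, seed = seed, missingness_rates = rates)
}

#' Derive a per-stage child seed from the master seed
#'
#' Each pipeline stage (simulation, missingness overlay, imputation,
#' bootstrap) draws its randomness from a distinct child seed obtained from
#' the master seed by a fixed offset, so stages are individually reproducible.
#'
#' @param master Master integer seed.
#' @param stage One of `"simulate"`, `"missingness"`, `"impute"`, `"bootstrap"`.
#' @return Integer seed (< 2^31).
#' @export
stage_seed <- function(master, stage = c("simulate", "missingness", "impute", "bootstrap")) {
  stage <- match.arg(stage)
  off <- c(simulate = 0L, missingness = 1013L, impute = 2027L, bootstrap = 3041L)[[stage]]
  as.integer((as.numeric(master) + off) %% .Machine$integer.max)
}

#' Read / write a cohort configuration as YAML
#'
#' @param config A [cohort_config()].
#' @param path File path.
#' @return `read_config()` returns a [cohort_config()]; `write_config()`
#'   returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  x <- unclass(config)
  x$arms <- lapply(x$arms, function(a) Filter(Negate(is.null), unclass(a)))
  x$wage_table <- as.list(x$wage_table)   # yaml drops names of atomic vectors
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  required <- c("arms", "seed")
  miss <- setdiff(required, names(x))
  if (length(miss))
    stop("read_config: missing config key(s): ", paste(miss, collapse = ", "), call. = FALSE)
  arms <- lapply(x$arms, function(a) do.call(arm_spec, a))
  x$arms <- NULL
  x$wage_table <- unlist(x$wage_table)
  x$partial_absence_range <- as.numeric(unlist(x$partial_absence_range))
  x$baseline_hazard <- as.numeric(unlist(x$baseline_hazard))
  x$benefit_baseline_prob <- as.numeric(unlist(x$benefit_baseline_prob))
  do.call(cohort_config, c(list(arms = arms), x))
}
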