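#' Micro-cost an intervention from resource use
#'
#' Bottom-up intervention costing: one-off training and mentoring costs are
#' amortized over the number of treated participants, per-participant
#' delivery time is valued at the deliverer's hourly rate, and an overhead
#' fraction is applied to the total.
#'
#' @param training_hours,training_rate Hours of provider training and the
#'   hourly rate (EUR) at which they are valued (one-off, amortized).
#' @param mentoring_hours,mentoring_rate Hours of supervision or mentoring
#'   over the delivery period and their hourly rate (one-off, amortized).
#' @param session_hours Provider time per delivered session (hours).
#' @param sessions_per_participant Mean number of sessions per participant.
#' @param delivery_rate Hourly rate (EUR) of the delivering provider.
#' @param overhead Overhead fraction applied to the subtotal (e.g. 0.2).
#' @param n_participants Number of participants the one-off costs are spread
#'   over (>= 1).
#' @return Cost per participant (EUR).
#' @export
micro_cost_intervention <- function(training_hours = 0, training_rate = 0,
                                    mentoring_hours = 0, mentoring_rate = 0,
                                    session_hours = 0, sessions_per_participant = 0,
                                    delivery_rate = 0, overhead = 0,
                                    n_participants) {
  if (missing(n_participants) || n_participants < 1)
    stop("micro_cost_intervention: 'n_participants' must be >= 1", call. = FALSE)
  vals <- c(training_hours, training_rate, mentoring_hours, mentoring_rate,
            session_hours, sessions_per_participant, delivery_rate, overhead)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("micro_cost_intervention: all inputs must be non-negative", call. = FALSE)
  fixed <- training_hours * training_rate + mentoring_hours * mentoring_rate
  per_head <- fixed / n_participants +
    session_hours * sessions_per_participant * delivery_rate
  per_head * (1 + overhead)
}

#' Value absenteeism by the human-capital approach
#'
#' Absence days are valued at the average daily wage stratified by sex, as in
#' official-statistics income tables.
#'
#' @param absence_days Days absent (vectorised); `NA` passes through.
#' @param sex Character vector matching names of `wage_table`.
#' @param wage_table Named numeric vector of daily wages (EUR/day).
#' @return Absenteeism cost (EUR).
#' @export
value_absenteeism <- function(absence_days, sex, wage_table) {
  if (any(!sex %in% names(wage_table)))
    stop("value_absenteeism: no wage entry for sex value(s): ",
         paste(unique(sex[!sex %in% names(wage_table)]), collapse = ", "),
         call. = FALSE)
  if (any(absence_days < 0, na.rm = TRUE))
    stop("value_absenteeism: negative absence days", call. = FALSE)
  absence_days * unname(wage_table[sex])
}

#' Value unpaid-work productivity losses
#'
#' @param hours_lost Hours of unpaid work lost (vectorised).
#' @param shadow_price EUR per hour of unpaid work.
#' @return Cost (EUR).
#' @export
value_unpaid_productivity <- function(hours_lost, shadow_price) {
  if (any(hours_lost < 0, na.rm = TRUE) || shadow_price < 0)
    stop("value_unpaid_productivity: negative inputs", call. = FALSE)
  hours_lost * shadow_price
}

#' Convert and index costs to 2021 euros
#'
#' Pure linear scaling: amount x price-index factor x exchange rate, so
#' conversion commutes with summation of cost components.
#'
#' @param amount Cost in source currency.
#' @param index_factor Price-index factor to the target year (default 1).
#' @param exchange_rate Units of EUR per unit of source currency.
#' @return Cost in indexed euros.
#' @export
convert_currency <- function(amount, index_factor = 1, exchange_rate = 1) {
  if (!is.finite(exchange_rate) || exchange_rate <= 0)
    stop("convert_currency: 'exchange_rate' must be positive", call. = FALSE)
  if (!is.finite(index_factor) || index_factor <= 0)
    stop("convert_currency: 'index_factor' must be positive", call. = FALSE)
  amount * index_factor * exchange_rate
}

#' Quality-adjusted life years over follow-up
#'
#' Two constructions are supported. `"single-point"` multiplies the utility
#' at the end of follow-up by the follow-up length in years (the literal
#' 12-month-measurement reading). `"auc-linear"` integrates the utility
#' trajectory by the trapezoid rule over the available timepoints, the
#' conventional area-under-the-curve QALY.
#'
#' @param utilities Numeric vector of utilities at `timepoints`.
#' @param timepoints Months at which the utilities were measured (same
#'   length as `utilities`). For `"single-point"` only the last value is
#'   used.
#' @param method `"single-point"` or `"auc-linear"`.
#' @param followup_months Follow-up horizon in months (default 12).
#' @return QALY (years).
#' @export
compute_qaly <- function(utilities, timepoints = c(0, 12),
                         method = c("single-point", "auc-linear"),
                         followup_months = 12) {
  method <- match.arg(method)
  ok <- is.finite(utilities)
  if (!any(ok)) stop("compute_qaly: no utility values supplied", call. = FALSE)
  utilities <- utilities[ok]
  timepoints <- timepoints[ok]
  if (method == "single-point") {
    utilities[length(utilities)] * followup_months / 12
  } else {
    if (length(utilities) == 1L) return(utilities * followup_months / 12)
    o <- order(timepoints)
    u <- utilities[o]; tp <- timepoints[o]
    sum(diff(tp) * (utils::head(u, -1) + utils::tail(u, -1)) / 2) / 12
  }
}

#' Per-participant QALY column for a cohort baseline table
#'
#' @param baseline Cohort baseline data frame with `utility_baseline` and
#'   `utility_12m`.
#' @param method QALY construction, see [compute_qaly()].
#' @return Numeric vector of QALYs (NA where the needed utilities are NA).
#' @export
cohort_qaly <- function(baseline, method = c("single-point", "auc-linear")) {
  method <- match.arg(method)
  if (method == "single-point") baseline$utility_12m
  else (baseline$utility_baseline + baseline$utility_12m) / 2
}

cost_components <- c("cost_intervention", "cost_healthcare_primary",
                     "cost_healthcare_secondary", "cost_absenteeism",
                     "cost_unpaid")

#' Arm-level cost table with unadjusted and adjusted differences
#'
#' Mirrors the canonical trial cost table: per-component arm means with
#' standard errors, and for each intervention arm the unadjusted and
#' covariate-adjusted mean difference versus the reference arm with
#' bias-corrected bootstrap percentile confidence intervals. Component
#' differences sum exactly to the total difference (linearity).
#'
#' @param baseline Complete (or singly-imputed) cohort baseline table; the
#'   first factor level of `arm` is the reference.
#' @param covariates Character vector of adjustment covariates (default the
#'   standard confounding set).
#' @param B Bootstrap replicates for the difference CIs.
#' @param seed Seed for the bootstrap.
#' @param conf Confidence level.
#' @return A data frame with one row per component x arm-contrast (plus the
#'   total), columns `component`, `comparison`, `mean_ref`, `mean_arm`,
#'   `diff_unadj`, `lcl_unadj`, `ucl_unadj`, `diff_adj`, `lcl_adj`, `ucl_adj`.
#' @export
cost_difference_table <- function(baseline,
                                  covariates = default_adjustment_set(),
                                  B = 1000, seed = 1, conf = 0.95) {
  comps <- c(cost_components, "cost_total")
  need <- c(comps, "arm", covariates)
  if (anyNA(baseline[, intersect(need, names(baseline))]))
    stop("cost_difference_table: missing values present; impute first (see mice_pmm)",
         call. = FALSE)
  arms <- levels(droplevels(factor(baseline$arm)))
  ref <- arms[1]
  out <- list()
  set.seed(seed)
  n <- nrow(baseline)
  idx_boot <- replicate(B, stratified_resample(baseline$arm), simplify = FALSE)
  for (comp in comps) {
    y <- baseline[[comp]]
    for (a in arms[-1]) {
      sel <- baseline$arm %in% c(ref, a)
      est_u <- mean(y[baseline$arm == a]) - mean(y[baseline$arm == ref])
      est_a <- adjusted_diff(baseline, comp, a, ref, covariates)
      bu <- ba <- numeric(B)
      for (b in seq_len(B)) {
        dbb <- baseline[idx_boot[[b]], ]
        yb <- dbb[[comp]]
        bu[b] <- mean(yb[dbb$arm == a]) - mean(yb[dbb$arm == ref])
        ba[b] <- adjusted_diff(dbb, comp, a, ref, covariates)
      }
      ci_u <- bc_ci(bu, est_u, conf)
      ci_a <- bc_ci(ba, est_a, conf)
      out[[length(out) + 1L]] <- data.frame(
        component = comp, comparison = paste(a, "vs", ref),
        mean_ref = mean(y[baseline$arm == ref]),
        mean_arm = mean(y[baseline$arm == a]),
        se_ref = stats::sd(y[baseline$arm == ref]) / sqrt(sum(baseline$arm == ref)),
        se_arm = stats::sd(y[baseline$arm == a]) / sqrt(sum(baseline$arm == a)),
        diff_unadj = est_u, lcl_unadj = ci_u[1], ucl_unadj = ci_u[2],
        diff_adj = est_a, lcl_adj = ci_a[1], ucl_adj = ci_a[2],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# covariate-adjusted arm difference from a single three-arm linear model
adjusted_diff <- function(d, outcome, a, ref, covariates) {
  f <- stats::reformulate(c("arm", covariates), response = outcome)
  fit <- stats::lm(f, data = d)
  cf <- stats::coef(fit)
  nm <- paste0("arm", a)
  if (!nm %in% names(cf)) return(NA_real_)
  unname(cf[nm])
}

# bias-corrected (BC) bootstrap percentile interval
bc_ci <- function(boot, est, conf = 0.95) {
  boot <- boot[is.finite(boot)]
  if (!length(boot) || stats::sd(boot) == 0) return(c(est, est))
  z0 <- stats::qnorm(pmin(pmax(mean(boot < est), 1 / length(boot)),
                          1 - 1 / length(boot)))
  za <- stats::qnorm((1 + c(-conf, conf)) / 2)
  probs <- stats::pnorm(2 * z0 + za)
  unname(stats::quantile(boot, probs, type = 6))
}

# resample row indices with replacement within each arm
stratified_resample <- function(arm) {
  unlist(lapply(split(seq_along(arm), arm),
                function(ix) ix[sample.int(length(ix), replace = TRUE)]),
         use.names = FALSE)
}

#' Default covariate adjustment set
#'
#' Age, sex, education level, sickness-absence days the previous year,
#' workability, baseline musculoskeletal health, physical activity and
#' employer follow-up.
#' @return Character vector of baseline column names.
#' @export
default_adjustment_set <- function() {
  c("age", "sex", "education", "prior_absence_days", "workability",
    "mskhq_0", "physical_activity", "employer_followup")
}
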