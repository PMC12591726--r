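#' Detect sustained return to work from a monthly absence panel
#'
#' Sustained RTW is the first four-week period of 50-100 percent return to
#' contracted work hours without relapse. On a monthly panel this is
#' operationalized as the first month `m` whose absence fraction is below
#' `threshold` and stays below it for the three following months. By default
#' the confirmation window is truncated at the end of follow-up, so a drop
#' sustained through the final month counts as an event (events can then
#' occur in months 10-12 of a 12-month panel); with
#' `require_full_window = TRUE` the full four months must be observed.
#' Participants with no qualifying month are censored at the end of
#' follow-up.
#'
#' @param panel Long person-month table with columns `id`, `month`,
#'   `absence_fraction` (a `trial_cohort` may be passed directly).
#' @param threshold Absence fraction below which a month qualifies
#'   (default 0.5).
#' @param require_full_window Logical; require all four window months to be
#'   observed within follow-up.
#' @param months Follow-up length; defaults to the maximum month in the
#'   panel. Panels shorter than this are rejected.
#' @return Data frame with one row per participant: `id`, `time` (months,
#'   censored records have `time = months`), `event` (1 = sustained RTW).
#' @export
sustained_rtw <- function(panel, threshold = 0.5, require_full_window = FALSE,
                          months = NULL) {
  if (inherits(panel, "trial_cohort")) panel <- panel$panel
  stopifnot(all(c("id", "month", "absence_fraction") %in% names(panel)))
  if (is.null(months)) months <- max(panel$month)
  sp <- split(panel[order(panel$id, panel$month), ], panel$id[order(panel$id, panel$month)])
  res <- lapply(sp, function(d) {
    if (nrow(d) < months)
      stop("sustained_rtw: panel for id ", d$id[1], " has ", nrow(d),
           " months; follow-up is ", months, call. = FALSE)
    t <- rtw_time(d$absence_fraction[seq_len(months)], threshold, require_full_window)
    data.frame(id = d$id[1], time = if (is.na(t)) months else t,
               event = as.integer(!is.na(t)))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$id), ]
}

# scan for the first qualifying (possibly end-truncated) 4-month window
rtw_time <- function(frac, threshold = 0.5, require_full_window = FALSE) {
  M <- length(frac)
  last_start <- if (require_full_window) M - 3L else M
  if (last_start < 1L) return(NA_integer_)
  for (m in seq_len(last_start)) {
    win <- m:min(m + 3L, M)
    if (all(frac[win] < threshold)) return(m)
  }
  NA_integer_
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples. The statistic is the number of pairs
#' `(x_i, y_j)` with `x_i > y_j` (ties counted one half). The p-value uses
#' exact enumeration when both samples have at most 8 untied observations,
#' otherwise the tie-corrected normal approximation.
#'
#' @param x,y Numeric samples (non-empty).
#' @return List with `U`, `p_value`, and `method`.
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (!length(x) || !length(y))
    stop("mann_whitney_u: empty sample", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && length(x) <= 8 && length(y) <= 8
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact))
  list(U = unname(wt$statistic), p_value = wt$p.value,
       method = if (exact) "exact" else "normal-approximation")
}

#' Arm differences in absence days by robust linear regression
#'
#' Fits a single linear model containing all arms (reference = first factor
#' level), unadjusted or adjusted for a covariate set, and returns the arm
#' coefficients as mean differences in days with 95 percent confidence
#' intervals. The default estimator is Huber M-estimation (tuning constant
#' 1.345); `method = "ols"` fits least squares with HC3 sandwich standard
#' errors as a sensitivity analysis.
#'
#' @param baseline Cohort baseline table with `absence_days` and `arm`.
#' @param covariates Optional character vector of adjustment covariates.
#' @param outcome Outcome column (default `"absence_days"`).
#' @param method `"huber"` or `"ols"`.
#' @param conf Confidence level.
#' @return Data frame of class `effect_estimate`: `comparison`, `estimate`,
#'   `lcl`, `ucl`, `p_value`, `scale`, `adjusted`, `model`.
#' @export
robust_linear_diff <- function(baseline, covariates = NULL,
                               outcome = "absence_days",
                               method = c("huber", "ols"), conf = 0.95) {
  method <- match.arg(method)
  baseline$arm <- droplevels(factor(baseline$arm))
  f <- stats::reformulate(c("arm", covariates), response = outcome)
  mf <- stats::model.frame(f, data = baseline)
  X <- stats::model.matrix(f, mf)
  check_collinearity(X)
  y <- stats::model.response(mf)
  if (stats::var(y) == 0) {
    warning("robust_linear_diff: outcome is constant; returning zero coefficients",
            call. = FALSE)
    arms <- levels(baseline$arm)[-1]
    return(effect_frame(paste(arms, "vs", levels(baseline$arm)[1]),
                        rep(0, length(arms)), rep(0, length(arms)),
                        rep(NA_real_, length(arms)),
                        "difference-in-days", !is.null(covariates), method, conf))
  }
  if (method == "huber") {
    fit <- MASS::rlm(f, data = baseline, psi = MASS::psi.huber, k = 1.345,
                     maxit = 100)
    cf <- summary(fit)$coefficients
    est <- cf[, "Value"]; se <- cf[, "Std. Error"]
  } else {
    fit <- stats::lm(f, data = baseline)
    vc <- sandwich::vcovHC(fit, type = "HC3")
    est <- stats::coef(fit); se <- sqrt(diag(vc))
  }
  keep <- grep("^arm", names(est))
  ref <- levels(baseline$arm)[1]
  comp <- paste(sub("^arm", "", names(est)[keep]), "vs", ref)
  effect_frame(comp, est[keep], se[keep], NULL, "difference-in-days",
               !is.null(covariates), method, conf)
}

check_collinearity <- function(X) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stop("collinear design columns: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

effect_frame <- function(comparison, est, se, p, scale, adjusted, model, conf = 0.95) {
  z <- stats::qnorm((1 + conf) / 2)
  if (is.null(p)) p <- 2 * stats::pnorm(-abs(est / se))
  out <- data.frame(comparison = comparison, estimate = unname(est),
                    lcl = unname(est - z * se), ucl = unname(est + z * se),
                    p_value = unname(p), scale = scale, adjusted = adjusted,
                    model = model, stringsAsFactors = FALSE)
  class(out) <- c("effect_estimate", "data.frame")
  rownames(out) <- NULL
  out
}

#' Kaplan-Meier estimate of time to sustained RTW
#'
#' Product-limit estimate with Greenwood variance and log-log confidence
#' intervals, evaluated at each month.
#'
#' @param outcomes Data frame with `time` and `event` (see [sustained_rtw()]);
#'   optionally a `group` argument for per-group curves.
#' @param group Optional grouping vector (e.g. arm labels).
#' @param conf Confidence level.
#' @return Data frame: (`group`,) `month`, `n_risk`, `n_event`, `surv`,
#'   `lcl`, `ucl`.
#' @export
kaplan_meier <- function(outcomes, group = NULL, conf = 0.95) {
  if (!nrow(outcomes)) stop("kaplan_meier: no records", call. = FALSE)
  if (is.null(group)) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = outcomes,
                             conf.type = "log-log", conf.int = conf)
    s <- summary(fit, times = sort(unique(outcomes$time)), extend = TRUE)
    return(data.frame(month = s$time, n_risk = s$n.risk, n_event = s$n.event,
                      surv = s$surv, lcl = s$lower, ucl = s$upper))
  }
  parts <- lapply(split(outcomes, group), kaplan_meier, conf = conf)
  out <- do.call(rbind, Map(function(g, d) cbind(group = g, d),
                            names(parts), parts))
  rownames(out) <- NULL
  out
}

#' Log-rank test across groups
#'
#' @param outcomes Data frame with `time` and `event`.
#' @param group Grouping vector with at least two non-empty levels.
#' @return List with `statistic` (chi-square), `df`, and `p_value`.
#' @export
log_rank <- function(outcomes, group) {
  group <- droplevels(factor(group))
  if (nlevels(group) < 2)
    stop("log_rank: need at least two non-empty groups", call. = FALSE)
  d <- cbind(outcomes, .g = group)
  sd <- survival::survdiff(survival::Surv(time, event) ~ .g, data = d)
  df <- length(sd$n) - 1
  list(statistic = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional hazards model for sustained RTW
#'
#' All arms enter one model (reference = first factor level); monthly event
#' times produce heavy ties, handled by the Efron approximation by default
#' (`ties = "breslow"` available).
#'
#' @param outcomes Data frame with `time`, `event`, aligned with `baseline`.
#' @param baseline Cohort baseline table supplying `arm` and covariates.
#' @param covariates Optional adjustment covariates.
#' @param ties `"efron"` or `"breslow"`.
#' @param conf Confidence level.
#' @return An `effect_estimate` data frame on the hazard-ratio scale.
#' @export
cox_ph <- function(outcomes, baseline, covariates = NULL,
                   ties = c("efron", "breslow"), conf = 0.95) {
  ties <- match.arg(ties)
  stopifnot(nrow(outcomes) == nrow(baseline))
  d <- cbind(outcomes, baseline[setdiff(names(baseline), names(outcomes))])
  d$arm <- droplevels(factor(d$arm))
  f <- stats::as.formula(paste("survival::Surv(time, event) ~",
                               paste(c("arm", covariates), collapse = " + ")))
  fit <- survival::coxph(f, data = d, ties = ties)
  if (!fit$iter || any(!is.finite(stats::coef(fit))))
    stop("cox_ph: partial-likelihood maximization failed", call. = FALSE)
  cf <- stats::coef(fit); se <- sqrt(diag(stats::vcov(fit)))
  keep <- grep("^arm", names(cf))
  z <- stats::qnorm((1 + conf) / 2)
  ref <- levels(d$arm)[1]
  out <- data.frame(
    comparison = paste(sub("^arm", "", names(cf)[keep]), "vs", ref),
    estimate = exp(unname(cf[keep])),
    lcl = exp(unname(cf[keep] - z * se[keep])),
    ucl = exp(unname(cf[keep] + z * se[keep])),
    p_value = 2 * stats::pnorm(-abs(unname(cf[keep] / se[keep]))),
    scale = "hazard-ratio", adjusted = !is.null(covariates),
    model = paste0("coxph-", ties), stringsAsFactors = FALSE)
  class(out) <- c("effect_estimate", "data.frame")
  out
}

#' Monthly wage-replacement benefit model
#'
#' Pooled person-month logistic regression of benefit receipt on arm and
#' month fixed effects (plus optional covariates), with variance clustered
#' on participant. Returns the odds ratio of each intervention arm versus
#' the reference.
#'
#' @param panel Long person-month table with `id`, `month`,
#'   `benefit_received` (a `trial_cohort` may be passed).
#' @param baseline Baseline table supplying `arm` and covariates (matched by
#'   `id`); ignored when `panel` is a `trial_cohort`.
#' @param covariates Optional adjustment covariates.
#' @param conf Confidence level.
#' @return An `effect_estimate` data frame on the odds-ratio scale.
#' @export
monthly_benefit_model <- function(panel, baseline = NULL, covariates = NULL,
                                  conf = 0.95) {
  if (inherits(panel, "trial_cohort")) {
    baseline <- panel$baseline
    panel <- panel$panel
  }
  stopifnot(!is.null(baseline))
  d <- merge(panel, baseline[, c("id", "arm", covariates), drop = FALSE], by = "id")
  d$arm <- droplevels(factor(d$arm))
  y <- as.integer(d$benefit_received)
  if (all(y == 0) || all(y == 1))
    stop("monthly_benefit_model: benefit outcome is constant", call. = FALSE)
  rhs <- c("arm", if (length(unique(d$month)) > 1) "factor(month)", covariates)
  f <- stats::reformulate(rhs, response = "benefit_received")
  fit <- stats::glm(f, data = d, family = stats::binomial())
  vc <- sandwich::vcovCL(fit, cluster = d$id)
  ct <- lmtest::coeftest(fit, vcov. = vc)
  keep <- grep("^arm", rownames(ct))
  z <- stats::qnorm((1 + conf) / 2)
  ref <- levels(d$arm)[1]
  out <- data.frame(
    comparison = paste(sub("^arm", "", rownames(ct)[keep]), "vs", ref),
    estimate = exp(ct[keep, 1]),
    lcl = exp(ct[keep, 1] - z * ct[keep, 2]),
    ucl = exp(ct[keep, 1] + z * ct[keep, 2]),
    p_value = ct[keep, 4],
    scale = "odds-ratio", adjusted = !is.null(covariates),
    model = "glm-logit-clustered", stringsAsFactors = FALSE)
  class(out) <- c("effect_estimate", "data.frame")
  rownames(out) <- NULL
  out
}

#' Linear mixed model for repeated musculoskeletal-health scores
#'
#' Scores at months 3, 6, 9 and 12 are modelled with fixed effects for arm,
#' time, their interaction, and the baseline score; repeated measures are
#' accounted for by a participant-level random intercept (default) or by a
#' generalized-least-squares fit with an unstructured within-participant
#' covariance. Returns the estimated arm-versus-reference difference in
#' points at each follow-up.
#'
#' @param baseline Cohort baseline table with columns `mskhq_0`, `mskhq_3`,
#'   `mskhq_6`, `mskhq_9`, `mskhq_12`, and `arm`.
#' @param covariance `"random_intercept"` or `"unstructured"`.
#' @param conf Confidence level.
#' @return An `effect_estimate` data frame with a `month` column.
#' @export
mskhq_mixed_model <- function(baseline,
                              covariance = c("random_intercept", "unstructured"),
                              conf = 0.95) {
  covariance <- match.arg(covariance)
  long <- mskhq_long(baseline)
  if (!nrow(long))
    stop("mskhq_mixed_model: no post-baseline scores available", call. = FALSE)
  long$arm <- droplevels(factor(long$arm))
  long$time_f <- droplevels(factor(long$month, levels = c(3, 6, 9, 12)))
  months_present <- as.numeric(levels(long$time_f))
  if (covariance == "random_intercept") {
    fit <- lme4::lmer(score ~ arm * time_f + mskhq_0 + (1 | id), data = long,
                      REML = TRUE)
    beta <- lme4::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
  } else {
    fit <- nlme::gls(score ~ arm * time_f + mskhq_0, data = long,
                     correlation = nlme::corSymm(form = ~ as.numeric(time_f) | id),
                     weights = nlme::varIdent(form = ~ 1 | time_f),
                     na.action = stats::na.omit)
    beta <- stats::coef(fit)
    V <- as.matrix(stats::vcov(fit))
  }
  arms <- levels(long$arm)[-1]
  ref <- levels(long$arm)[1]
  z <- stats::qnorm((1 + conf) / 2)
  rows <- list()
  for (a in arms) {
    for (m in months_present) {
      cvec <- stats::setNames(numeric(length(beta)), names(beta))
      cvec[paste0("arm", a)] <- 1
      inm <- paste0("arm", a, ":time_f", m)
      if (inm %in% names(beta)) cvec[inm] <- 1
      est <- sum(cvec * beta)
      se <- sqrt(drop(t(cvec) %*% V %*% cvec))
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = paste(a, "vs", ref), month = m, estimate = est,
        lcl = est - z * se, ucl = est + z * se,
        p_value = 2 * stats::pnorm(-abs(est / se)),
        scale = "score-points", adjusted = TRUE,
        model = paste0("lmm-", covariance), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("effect_estimate", "data.frame")
  out
}

# wide baseline -> long post-baseline MSK-HQ table; participants with no
# post-baseline score drop out here
mskhq_long <- function(baseline) {
  cols <- paste0("mskhq_", c(3, 6, 9, 12))
  stopifnot(all(c(cols, "mskhq_0", "arm", "id") %in% names(baseline)))
  long <- stats::reshape(
    baseline[, c("id", "arm", "mskhq_0", cols)],
    direction = "long", varying = cols, v.names = "score",
    times = c(3, 6, 9, 12), timevar = "month", idvar = "id")
  long <- long[!is.na(long$score) & !is.na(long$mskhq_0), ]
  rownames(long) <- NULL
  long
}
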