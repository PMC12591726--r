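# brute-force window scan used as the detector oracle
oracle_rtw <- function(frac, threshold = 0.5) {
  M <- length(frac)
  for (m in 1:M) {
    ok <- TRUE
    for (j in m:min(m + 3, M)) if (!(frac[j] < threshold)) ok <- FALSE
    if (ok) return(m)
  }
  NA_integer_
}

test_that("sustained-RTW detector finds the first relapse-free window", {
  # never below threshold -> censored at 12
  p <- data.frame(id = 1, month = 1:12, absence_fraction = rep(1, 12))
  out <- sustained_rtw(p)
  expect_equal(out$time, 12); expect_equal(out$event, 0L)

  # absent months 1-5, zero thereafter -> event at month 6
  p$absence_fraction <- c(rep(1, 5), rep(0, 7))
  out <- sustained_rtw(p)
  expect_equal(out$time, 6); expect_equal(out$event, 1L)

  # dip at month 4, relapse at 5, recovery from 7 -> event at month 7
  p$absence_fraction <- c(1, 1, 1, 0.3, 1, 1, rep(0, 6))
  out <- sustained_rtw(p)
  expect_equal(out$time, 7); expect_equal(out$event, 1L)

  # random panels agree with the brute-force scan
  set.seed(42)
  for (r in 1:200) {
    frac <- sample(c(0, 0.3, 0.6, 1), 12, replace = TRUE)
    got <- sustained_rtw(
      data.frame(id = 1, month = 1:12, absence_fraction = frac))
    want <- oracle_rtw(frac)
    if (is.na(want)) expect_equal(got$event, 0L)
    else expect_equal(got$time, want)
  }

  # strict full-window variant censors late transitions
  p$absence_fraction <- c(rep(1, 10), 0, 0)
  expect_equal(sustained_rtw(p)$time, 11)
  expect_equal(sustained_rtw(p, require_full_window = TRUE)$event, 0L)

  # short panel is rejected
  expect_error(sustained_rtw(p[1:6, ], months = 12), "6 months")
})

test_that("Mann-Whitney U matches exhaustive pair counting", {
  # identical samples: U = n1*n2/2 by symmetry (ties -> half counts)
  x <- c(1, 2, 3, 4)
  expect_equal(mann_whitney_u(x, x)$U, 8)
  # complete separation
  expect_equal(mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$U, 0)
  # interleaved: count pairs by brute force
  x <- c(1, 3, 5); y <- c(2, 4, 6)
  u_brute <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  expect_equal(u_brute, 3)
  expect_equal(mann_whitney_u(x, y)$U, u_brute)
  # exact and normal-approximate p agree closely at n1 = n2 = 8, no ties
  set.seed(1)
  x <- sample(seq(1, 160, by = 1), 8); y <- sample(seq(0.5, 159.5, by = 1), 8)
  res <- mann_whitney_u(x, y)
  expect_equal(res$method, "exact")
  u <- res$U; n1 <- 8; n2 <- 8
  mu <- n1 * n2 / 2; sg <- sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
  p_norm <- 2 * min(pnorm((u + 0.5 - mu) / sg), 1 - pnorm((u - 0.5 - mu) / sg))
  expect_lt(abs(res$p_value - min(p_norm, 1)), 0.01)
  expect_error(mann_whitney_u(numeric(0), 1:3), "empty")
})

test_that("robust regression recovers arm differences and flags degeneracies", {
  # null: two arms from identical parameters
  cfg <- two_arm_config(n = 1500, seed = 31)
  b <- generate_cohort(cfg)$baseline
  est <- robust_linear_diff(b)
  expect_true(est$lcl < 0 && 0 < est$ucl)
  # OLS sensitivity path agrees in direction and magnitude
  est_ols <- robust_linear_diff(b, method = "ols")
  expect_lt(abs(est$estimate - est_ols$estimate), 5)

  # constant outcome: zero coefficients plus warning
  b$absence_days <- 10
  expect_warning(z <- robust_linear_diff(b), "constant")
  expect_equal(z$estimate, 0)

  # collinear covariates are named
  b2 <- generate_cohort(cfg)$baseline
  b2$age_copy <- b2$age
  expect_error(robust_linear_diff(b2, covariates = c("age", "age_copy")),
               "age_copy")
})

test_that("Kaplan-Meier matches the hand-computed product limit", {
  # no events: survival 1 throughout
  km <- kaplan_meier(surv_df(c(12, 12, 12), c(0, 0, 0)))
  expect_true(all(km$surv == 1))

  # events at 2 and 3, censored at 5 and 12:
  # S(2) = 3/4, S(3) = 3/4 * 2/3 = 1/2
  km <- kaplan_meier(surv_df(c(2, 3, 5, 12), c(1, 1, 0, 0)))
  expect_equal(km$surv[km$month == 3], 0.5)
  expect_equal(km$surv[km$month == 2], 0.75)

  # survival is non-increasing and within [0, 1]; with no censoring it is
  # the empirical survival function
  set.seed(7)
  t <- sample(1:12, 60, replace = TRUE)
  km <- kaplan_meier(surv_df(t, rep(1, 60)))
  expect_true(all(diff(km$surv) <= 1e-12))
  expect_true(all(km$surv >= 0 & km$surv <= 1))
  emp <- vapply(km$month, function(m) mean(t > m), numeric(1))
  expect_equal(km$surv, emp)
})

test_that("log-rank statistic equals the hand enumeration", {
  # a group against itself: statistic 0
  o <- surv_df(c(2, 4, 6, 8), c(1, 1, 1, 0))
  both <- rbind(o, o); g <- rep(c("a", "b"), each = 4)
  expect_lt(log_rank(both, g)$statistic, 1e-10)

  # 6 subjects, hand-computed O-E/V
  o6 <- surv_df(c(1, 2, 3, 4, 5, 6), c(1, 1, 1, 1, 1, 0))
  g6 <- c("a", "b", "a", "b", "a", "b")
  # enumerate event times: observed vs expected in group a under the null
  O <- 0; E <- 0; V <- 0
  for (tm in sort(unique(o6$time[o6$event == 1]))) {
    at_risk <- o6$time >= tm
    n <- sum(at_risk); na <- sum(at_risk & g6 == "a")
    d <- sum(o6$time == tm & o6$event == 1)
    da <- sum(o6$time == tm & o6$event == 1 & g6 == "a")
    O <- O + da
    E <- E + d * na / n
    if (n > 1) V <- V + d * (na / n) * (1 - na / n) * (n - d) / (n - 1)
  }
  expect_equal(log_rank(o6, g6)$statistic, (O - E)^2 / V, tolerance = 1e-10)

  expect_error(log_rank(o6, rep("a", 6)), "two")

  # power: generated arms with HR 1.3 at n = 2000/arm reject in most replicates
  set.seed(99)
  S0 <- cumprod(1 - default_monthly_hazard())
  rej <- replicate(100, {
    draw <- function(S) {
      pm <- c(-diff(c(1, S)), S[12])
      m <- sample.int(13, 2000, replace = TRUE, prob = pm)
      data.frame(time = pmin(m, 12), event = as.integer(m <= 12))
    }
    d <- rbind(draw(S0), draw(S0^1.3))
    d$id <- seq_len(nrow(d))
    log_rank(d, rep(c("a", "b"), each = 2000))$p_value < 0.05
  })
  expect_gte(mean(rej), 0.8)
})

test_that("Cox coefficients agree with brute-force partial likelihood", {
  # 5 subjects, no ties: maximize the written partial likelihood directly
  time <- c(1, 2, 3, 4, 5); event <- c(1, 1, 1, 1, 0)
  x <- c(1, 0, 1, 0, 0)
  neg_logpl <- function(b) {
    s <- 0
    for (i in which(event == 1)) {
      rs <- which(time >= time[i])
      s <- s - (b * x[i] - log(sum(exp(b * x[rs]))))
    }
    s
  }
  b_oracle <- optimize(neg_logpl, c(-5, 5))$minimum
  d <- data.frame(id = 1:5, time = time, event = event,
                  arm = factor(ifelse(x == 1, "B", "A")))
  fit <- cox_ph(d[, c("id", "time", "event")], d)
  expect_equal(log(fit$estimate), b_oracle, tolerance = 1e-4)

  # null data: HR within CI of 1
  cfg <- two_arm_config(n = 1200, seed = 41)
  co <- generate_cohort(cfg)
  rtw <- sustained_rtw(co); rtw <- rtw[match(co$baseline$id, rtw$id), ]
  fit0 <- cox_ph(rtw, co$baseline)
  expect_true(fit0$lcl < 1 && 1 < fit0$ucl)
})

test_that("Cox recovers the generator hazard ratio at scale", {
  cfg <- two_arm_config(n = 5000, seed = 43, hr = 1.27)
  co <- generate_cohort(cfg)
  rtw <- sustained_rtw(co); rtw <- rtw[match(co$baseline$id, rtw$id), ]
  fit <- cox_ph(rtw, co$baseline)
  expect_lt(abs(fit$estimate - 1.27) / 1.27, 0.10)
  # Breslow tie handling is available and close
  fitb <- cox_ph(rtw, co$baseline, ties = "breslow")
  expect_lt(abs(fit$estimate - fitb$estimate), 0.1)
})

test_that("single-month benefit model reduces to ordinary logistic regression", {
  # 6-row toy, single month: compare against a likelihood grid + refine
  d <- data.frame(id = 1:6, month = 1,
                  benefit_received = c(1, 1, 0, 1, 0, 0))
  b <- data.frame(id = 1:6, arm = factor(rep(c("A", "B"), each = 3)))
  fit <- monthly_benefit_model(d, b)
  nll <- function(th) {
    eta <- th[1] + th[2] * (b$arm == "B")
    -sum(d$benefit_received * eta - log(1 + exp(eta)))
  }
  gr <- expand.grid(b0 = seq(-3, 3, 0.05), b1 = seq(-4, 4, 0.05))
  start <- unlist(gr[which.min(apply(gr, 1, nll)), ])
  opt <- optim(start, nll)
  expect_equal(log(fit$estimate), unname(opt$par[2]), tolerance = 1e-2)

  # degenerate outcomes are rejected
  d$benefit_received <- 1
  expect_error(monthly_benefit_model(d, b), "constant")

  # identical arms: OR within CI of 1
  cfg <- two_arm_config(n = 800, seed = 47)
  co <- generate_cohort(cfg)
  f0 <- monthly_benefit_model(co)
  expect_true(f0$lcl < 1 && 1 < f0$ucl)
})

test_that("mixed model equals closed-form cell means on balanced toy data", {
  # two arms x two timepoints, complete and balanced, baseline cloned across
  # arms so it is orthogonal to the arm contrast
  set.seed(5)
  n <- 40
  base_scores <- round(runif(n, 15, 40))
  mk <- function(armlab, eff3, eff6) {
    data.frame(id = paste0(armlab, 1:n), arm = armlab, mskhq_0 = base_scores,
               mskhq_3 = base_scores + eff3 + round(rnorm(n, 0, 3)),
               mskhq_6 = base_scores + eff6 + round(rnorm(n, 0, 3)),
               mskhq_9 = NA_real_, mskhq_12 = NA_real_)
  }
  toy <- rbind(mk("A", 2, 4), mk("B", 5, 9))
  fit <- suppressWarnings(suppressMessages(mskhq_mixed_model(toy)))
  cell <- function(armlab, m) mean(toy[[paste0("mskhq_", m)]][toy$arm == armlab])
  for (m in c(3, 6)) {
    want <- cell("B", m) - cell("A", m)
    got <- fit$estimate[fit$month == m]
    expect_equal(got, want, tolerance = 1e-6)
  }

  # unstructured-covariance variant exists and agrees on balanced data
  fit2 <- mskhq_mixed_model(toy, covariance = "unstructured")
  expect_equal(fit2$estimate[fit2$month == 6], fit$estimate[fit$month == 6],
               tolerance = 1e-4)
})

test_that("mixed model recovers a generated MSK-HQ shift and nulls", {
  # no group effect: interaction contrasts cover zero at every timepoint
  cfg <- two_arm_config(n = 600, seed = 53)
  b <- generate_cohort(cfg)$baseline
  fit0 <- mskhq_mixed_model(b)
  expect_true(all(fit0$lcl < 0 & 0 < fit0$ucl))

  # +3-point shift at 12 months recovered within +-0.5
  arms <- list(arm_spec("A", 2000), arm_spec("B", 2000, mskhq_shift_12m = 3))
  cfg <- cohort_config(arms, seed = 55, missingness_rates = list())
  b <- generate_cohort(cfg)$baseline
  fit <- mskhq_mixed_model(b)
  expect_lt(abs(fit$estimate[fit$month == 12] - 3), 0.5)
})
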