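test_that("SUR with identical regressors equals per-equation least squares", {
  b <- tiny_cohort(n = 80, seed = 81)$baseline
  d <- prepare_ce_columns(b, "days")
  fit <- sur_fit(d, "ce_cost", "ce_effect", covariates_cost = c("age", "sex"))
  expect_equal(fit$method, "ols")
  lm1 <- lm(ce_cost ~ arm + age + sex, data = d)
  lm2 <- lm(ce_effect ~ arm + age + sex, data = d)
  expect_equal(fit$coef_cost, coef(lm1), tolerance = 1e-10)
  expect_equal(fit$coef_effect, coef(lm2), tolerance = 1e-10)
})

test_that("cross-equation residual covariance is near zero when built so", {
  set.seed(3)
  n <- 4000
  d <- data.frame(arm = factor(rep(c("A", "B"), each = n / 2)),
                  ce_cost = rnorm(n), ce_effect = rnorm(n))
  fit <- sur_fit(d, "ce_cost", "ce_effect")
  rho <- fit$sigma[1, 2] / sqrt(fit$sigma[1, 1] * fit$sigma[2, 2])
  expect_lt(abs(rho), 3 / sqrt(n))
})

test_that("FGLS with distinct regressors matches the stacked GLS oracle", {
  set.seed(4)
  d <- data.frame(arm = factor(rep(c("A", "B"), 4)),
                  x1 = rnorm(8), x2 = rnorm(8))
  d$ce_cost <- 1 + 2 * (d$arm == "B") + 0.5 * d$x1 + rnorm(8, 0, 0.3)
  d$ce_effect <- -1 + 1 * (d$arm == "B") - 0.2 * d$x2 + rnorm(8, 0, 0.3)
  fit <- sur_fit(d, "ce_cost", "ce_effect",
                 covariates_cost = "x1", covariates_effect = "x2")
  expect_equal(fit$method, "fgls")
  # brute-force stacked GLS with the same estimated error covariance
  X1 <- model.matrix(~ arm + x1, d); X2 <- model.matrix(~ arm + x2, d)
  X <- rbind(cbind(X1, matrix(0, 8, ncol(X2))),
             cbind(matrix(0, 8, ncol(X1)), X2))
  y <- c(d$ce_cost, d$ce_effect)
  Omega_inv <- kronecker(solve(fit$sigma), diag(8))
  beta <- solve(t(X) %*% Omega_inv %*% X, t(X) %*% Omega_inv %*% y)
  expect_equal(unname(c(fit$coef_cost, fit$coef_effect)), unname(drop(beta)),
               tolerance = 1e-8)

  expect_error(sur_fit(cbind(d, x1b = d$x1), "ce_cost", "ce_effect",
                       covariates_cost = c("x1", "x1b")), "collinear")
})

test_that("bootstrap clouds are reproducible and consistent", {
  b <- tiny_cohort(n = 60, seed = 83)$baseline
  d <- prepare_ce_columns(b, "days")
  c1 <- bootstrap_ce(d, "ce_cost", "ce_effect", B = 2, seed = 7)
  c2 <- bootstrap_ce(d, "ce_cost", "ce_effect", B = 2, seed = 7)
  expect_identical(c1, c2)
  expect_equal(nrow(c1), 2L * 2L)  # two replicates x two comparisons

  # degenerate data: zero-variance cloud at the point estimate
  d0 <- d
  d0$ce_cost <- 100; d0$ce_effect <- -10
  c0 <- bootstrap_ce(d0, "ce_cost", "ce_effect", B = 50, seed = 8)
  expect_equal(unique(round(c0$delta_C, 10)), 0)
  expect_equal(unique(round(c0$delta_E, 10)), 0)

  # Gaussian data: bootstrap SE of delta_C within 10% of the analytic SE
  set.seed(9)
  n <- 150
  g <- data.frame(arm = factor(rep(c("A", "B"), each = n)),
                  ce_cost = c(rnorm(n, 0, 4), rnorm(n, 1, 4)),
                  ce_effect = rnorm(2 * n))
  cl <- bootstrap_ce(g, "ce_cost", "ce_effect", B = 2000, seed = 10)
  se_boot <- sd(cl$delta_C)
  v <- function(a) var(g$ce_cost[g$arm == a]) * (n - 1) / n / n
  se_analytic <- sqrt(v("A") + v("B"))
  expect_lt(abs(se_boot - se_analytic) / se_analytic, 0.10)

  # cloud mean within 2 Monte-Carlo SEs of the full-sample point estimate
  point <- sur_fit(g, "ce_cost", "ce_effect")$delta$delta_C
  expect_lt(abs(mean(cl$delta_C) - point), 2 * se_boot / sqrt(2000) * 3 + 0.05)
})

test_that("ICER ratio and dominance tags follow the sign conventions", {
  r <- icer(-1293, 19.2)
  expect_equal(r$icer, -1293 / 19.2)
  expect_equal(r$tag, "dominant")
  expect_equal(icer(-1110, 11.4)$icer, -1110 / 11.4)
  expect_equal(icer(0, 5), list(icer = 0, tag = "dominant"))
  expect_equal(icer(10, 0)$tag, "undefined")
  expect_true(is.na(icer(10, 0)$icer))
  expect_equal(icer(500, -2)$tag, "dominated")
  expect_equal(icer(-500, -2)$tag, "tradeoff")
})

test_that("CE-plane quadrants sum to 100 and honour the tie rule", {
  cl <- data.frame(delta_C = -1, delta_E = 1)
  q <- ce_plane_distribution(cl)
  expect_equal(q$SE, 100)
  # zero effect with negative cost falls in SE (favourable side)
  q0 <- ce_plane_distribution(data.frame(delta_C = -1, delta_E = 0))
  expect_equal(q0$SE, 100)

  # symmetric Gaussian cloud: each quadrant near 25%
  set.seed(11)
  cl <- data.frame(delta_C = rnorm(20000), delta_E = rnorm(20000))
  q <- ce_plane_distribution(cl)
  expect_equal(q$NE + q$SE + q$SW + q$NW, 100, tolerance = 1e-9)
  for (col in c("NE", "SE", "SW", "NW"))
    expect_lt(abs(q[[col]] - 25), 1.5)
  expect_error(ce_plane_distribution(cl[0, ]), "empty")
})

test_that("CEAC hits its formula limits and is monotone for positive effects", {
  set.seed(12)
  cl <- data.frame(delta_C = rnorm(5000, -1, 2), delta_E = abs(rnorm(5000, 2, 1)))
  grid <- c(0, 1, 5, 50, 1e9)
  cc <- ceac(cl, grid)
  expect_equal(cc$p_ce[cc$lambda == 0], mean(cl$delta_C < 0))
  expect_equal(cc$p_ce[cc$lambda == 1e9], mean(cl$delta_E > 0))
  # non-decreasing in lambda when all delta_E >= 0
  expect_true(all(diff(cc$p_ce) >= 0))
  expect_true(all(cc$p_ce >= 0 & cc$p_ce <= 1))
  expect_error(ceac(cl, c(3, 2, 1)), "increasing")
  g <- wtp_grid("days")
  expect_true(all(diff(g) > 0) && g[1] == 0 && max(g) == 500)
})

test_that("ROI metrics reproduce the printed formulas and their identity", {
  m <- cba_metrics(5278, 53)
  expect_equal(m$net_benefit, 5225)
  expect_equal(m$bcr, 5278 / 53)
  expect_equal(m$roi, (5278 - 53) / 53 * 100)

  m2 <- cba_metrics(7293, 78)
  expect_equal(m2$net_benefit, 7215)
  expect_equal(m2$bcr, 93.5, tolerance = 1e-3)
  expect_equal(m2$roi, 9250, tolerance = 1e-3)

  # benefits = costs: NB 0, BCR 1, ROI 0
  m3 <- cba_metrics(100, 100)
  expect_equal(m3$net_benefit, 0); expect_equal(m3$bcr, 1)
  expect_equal(m3$roi, 0)

  # identity ROI = (BCR - 1) x 100 over random inputs
  set.seed(13)
  for (i in 1:50) {
    bb <- runif(1, -1000, 10000); cc <- runif(1, 1, 500)
    mm <- cba_metrics(bb, cc)
    expect_equal(mm$roi, (mm$bcr - 1) * 100, tolerance = 1e-10)
  }

  # zero costs: NB defined, ratios tagged undefined
  m4 <- cba_metrics(10, 0)
  expect_equal(m4$net_benefit, 10)
  expect_true(is.na(m4$bcr) && m4$tag == "undefined")
})

test_that("probability of positive return counts bootstrap draws", {
  expect_equal(prob_positive_return(rep(5, 200)), 1)
  set.seed(14)
  sym <- rnorm(20000)
  expect_lt(abs(prob_positive_return(sym) - 0.5), 0.02)
  expect_error(prob_positive_return(rnorm(50)), "100")
})
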