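#' Seemingly unrelated regression of costs and effects
#'
#' Estimates the cost and effect equations jointly, accounting for the
#' correlation between their residuals. With identical regressor sets the
#' SUR coefficients coincide with per-equation least squares (the classical
#' result), and the cross-equation residual covariance is estimated and
#' carried into the joint coefficient covariance `Sigma (x) (X'X)^-1`. With
#' distinct regressor sets a one-step feasible GLS estimator is used, with
#' the residual covariance estimated from the per-equation least-squares
#' fits.
#'
#' @param data Data frame with `arm` (reference = first level), the cost and
#'   effect columns, and any covariates.
#' @param cost_col,effect_col Column names of the per-participant cost and
#'   effect.
#' @param covariates_cost,covariates_effect Optional covariate sets for the
#'   two equations (effect defaults to the cost set).
#' @return Object of class `sur_fit`: `delta` (per intervention arm:
#'   `comparison`, `delta_C`, `se_C`, `delta_E`, `se_E`, `cov_CE`),
#'   `sigma` (2x2 residual covariance), `coef_cost`, `coef_effect`,
#'   `method` (`"ols"` or `"fgls"`).
#' @export
sur_fit <- function(data, cost_col, effect_col,
                    covariates_cost = NULL,
                    covariates_effect = covariates_cost) {
  data$arm <- droplevels(factor(data$arm))
  f1 <- stats::reformulate(c("arm", covariates_cost))
  f2 <- stats::reformulate(c("arm", covariates_effect))
  X1 <- stats::model.matrix(f1, data)
  X2 <- stats::model.matrix(f2, data)
  check_collinearity(X1); check_collinearity(X2)
  y1 <- data[[cost_col]]; y2 <- data[[effect_col]]
  if (anyNA(y1) || anyNA(y2))
    stop("sur_fit: cost/effect contain missing values; impute first", call. = FALSE)
  n <- nrow(X1)
  fit1 <- stats::lm.fit(X1, y1)
  fit2 <- stats::lm.fit(X2, y2)
  r1 <- fit1$residuals; r2 <- fit2$residuals
  p1 <- ncol(X1); p2 <- ncol(X2)
  sigma <- matrix(c(sum(r1 * r1) / (n - p1), sum(r1 * r2) / (n - (p1 + p2) / 2),
                    sum(r1 * r2) / (n - (p1 + p2) / 2), sum(r2 * r2) / (n - p2)),
                  2, 2)
  identical_X <- identical(colnames(X1), colnames(X2)) &&
    isTRUE(all.equal(unname(X1), unname(X2)))
  if (identical_X) {
    b1 <- fit1$coefficients; b2 <- fit2$coefficients
    V <- kronecker(sigma, solve(crossprod(X1)))
    method <- "ols"
  } else {
    Si <- solve(sigma)
    A <- rbind(cbind(Si[1, 1] * crossprod(X1), Si[1, 2] * crossprod(X1, X2)),
               cbind(Si[2, 1] * crossprod(X2, X1), Si[2, 2] * crossprod(X2)))
    bvec <- c(Si[1, 1] * crossprod(X1, y1) + Si[1, 2] * crossprod(X1, y2),
              Si[2, 1] * crossprod(X2, y1) + Si[2, 2] * crossprod(X2, y2))
    V <- solve(A)
    beta <- drop(V %*% bvec)
    b1 <- stats::setNames(beta[seq_len(p1)], colnames(X1))
    b2 <- stats::setNames(beta[p1 + seq_len(p2)], colnames(X2))
    method <- "fgls"
  }
  arms <- levels(data$arm)[-1]
  ref <- levels(data$arm)[1]
  rows <- lapply(arms, function(a) {
    nm <- paste0("arm", a)
    i1 <- match(nm, colnames(X1)); i2 <- match(nm, colnames(X2))
    j1 <- i1; j2 <- p1 + i2
    data.frame(comparison = paste(a, "vs", ref),
               delta_C = unname(b1[nm]), se_C = sqrt(V[j1, j1]),
               delta_E = unname(b2[nm]), se_E = sqrt(V[j2, j2]),
               cov_CE = V[j1, j2], stringsAsFactors = FALSE)
  })
  structure(list(delta = do.call(rbind, rows), sigma = sigma,
                 coef_cost = b1, coef_effect = b2, method = method,
                 n = n),
            class = "sur_fit")
}

#' @export
print.sur_fit <- function(x, ...) {
  cat("SUR cost/effect fit (", x$method, "), n = ", x$n, "\n", sep = "")
  print(x$delta, row.names = FALSE)
  invisible(x)
}

#' Bootstrap cloud of incremental costs and effects
#'
#' Nonparametric bootstrap: participants are resampled with replacement
#' within each arm (preserving arm sizes) and the SUR estimator is applied
#' per replicate. With an [mice_pmm()] imputation stack, `B` is split evenly
#' over the completed datasets (resampling within each) and the clouds are
#' pooled; the alternative nesting - re-imputing inside each bootstrap
#' resample of the incomplete data - is available via
#' `nesting = "impute_within_bootstrap"`.
#'
#' @param data A complete data frame, or an `imputation_stack`.
#' @param cost_col,effect_col,covariates_cost,covariates_effect As in
#'   [sur_fit()].
#' @param B Total bootstrap replicates (>= 100 for downstream summaries;
#'   smaller values allowed for smoke checks).
#' @param seed Seed; the cloud is deterministic given it.
#' @param nesting Bootstrap/imputation nesting, see above.
#' @param incomplete_data Original incomplete data (only for
#'   `"impute_within_bootstrap"`).
#' @param imputation_args List of arguments passed to [mice_pmm()] under
#'   `"impute_within_bootstrap"`.
#' @return Data frame of class `ce_cloud`: `replicate`, `comparison`,
#'   `delta_C`, `delta_E`.
#' @export
bootstrap_ce <- function(data, cost_col, effect_col,
                         covariates_cost = NULL,
                         covariates_effect = covariates_cost,
                         B = 2000, seed = 1,
                         nesting = c("within_imputation", "impute_within_bootstrap"),
                         incomplete_data = NULL,
                         imputation_args = list()) {
  nesting <- match.arg(nesting)
  set.seed(seed)
  if (inherits(data, "imputation_stack") && nesting == "within_imputation") {
    Bm <- ceiling(B / data$M)
    clouds <- lapply(seq_len(data$M), function(m)
      boot_cloud(completed(data, m), cost_col, effect_col,
                 covariates_cost, covariates_effect, Bm,
                 rep_offset = (m - 1) * Bm))
    out <- do.call(rbind, clouds)
  } else if (nesting == "impute_within_bootstrap") {
    if (is.null(incomplete_data))
      stop("bootstrap_ce: supply 'incomplete_data' for impute_within_bootstrap",
           call. = FALSE)
    rows <- vector("list", B)
    for (b in seq_len(B)) {
      idx <- stratified_resample(incomplete_data$arm)
      db <- incomplete_data[idx, ]
      st <- do.call(mice_pmm, c(list(data = db, M = 2,
                                     seed = sample.int(2^30, 1)),
                                imputation_args))
      d1 <- completed(st, 1)
      fit <- sur_fit(d1, cost_col, effect_col, covariates_cost, covariates_effect)
      rows[[b]] <- cbind(replicate = b, fit$delta[, c("comparison", "delta_C", "delta_E")])
    }
    out <- do.call(rbind, rows)
  } else {
    out <- boot_cloud(data, cost_col, effect_col,
                      covariates_cost, covariates_effect, B, 0L)
  }
  rownames(out) <- NULL
  class(out) <- c("ce_cloud", "data.frame")
  out
}

boot_cloud <- function(data, cost_col, effect_col,
                       covariates_cost, covariates_effect, B, rep_offset) {
  data$arm <- droplevels(factor(data$arm))
  f1 <- stats::reformulate(c("arm", covariates_cost))
  f2 <- stats::reformulate(c("arm", covariates_effect))
  same <- identical(covariates_cost, covariates_effect)
  X1 <- stats::model.matrix(f1, data)
  X2 <- if (same) X1 else stats::model.matrix(f2, data)
  y1 <- data[[cost_col]]; y2 <- data[[effect_col]]
  arms <- levels(data$arm)[-1]
  ref <- levels(data$arm)[1]
  nm <- paste0("arm", arms)
  i1 <- match(nm, colnames(X1)); i2 <- match(nm, colnames(X2))
  rows <- vector("list", B)
  arm_idx <- split(seq_len(nrow(data)), data$arm)
  redrawn <- 0L
  for (b in seq_len(B)) {
    for (try in 1:100) {
      # resampling within arm preserves arm sizes; a redraw is only needed
      # when a covariate turns collinear in the replicate
      idx <- unlist(lapply(arm_idx, function(ix)
        ix[sample.int(length(ix), replace = TRUE)]), use.names = FALSE)
      if (same) {
        cf <- tryCatch(stats::lm.fit(X1[idx, , drop = FALSE],
                                     cbind(y1[idx], y2[idx]))$coefficients,
                       error = function(e) NULL)
        if (is.null(cf) || anyNA(cf[c(i1, i2), ])) { redrawn <- redrawn + 1L; next }
        dC <- cf[i1, 1]; dE <- cf[i2, 2]
      } else {
        dC <- stats::lm.fit(X1[idx, , drop = FALSE], y1[idx])$coefficients[i1]
        dE <- stats::lm.fit(X2[idx, , drop = FALSE], y2[idx])$coefficients[i2]
        if (anyNA(c(dC, dE))) { redrawn <- redrawn + 1L; next }
      }
      break
    }
    rows[[b]] <- data.frame(replicate = rep_offset + b,
                            comparison = paste(arms, "vs", ref),
                            delta_C = unname(dC), delta_E = unname(dE),
                            stringsAsFactors = FALSE)
  }
  if (redrawn > 0)
    message("bootstrap_ce: ", redrawn, " degenerate replicate(s) redrawn")
  do.call(rbind, rows)
}

#' Incremental cost-effectiveness ratio with dominance tag
#'
#' @param delta_C Incremental cost (EUR).
#' @param delta_E Incremental effect (QALY gained or absence days averted).
#' @return List: `icer` (EUR per effect unit; `NA` when `delta_E = 0`),
#'   `tag` - `"dominant"` (cheaper and at least as costly-neutral, more
#'   effective), `"dominated"` (costlier, less or equally effective),
#'   `"undefined"` (`delta_E = 0`), or `"tradeoff"`.
#' @export
icer <- function(delta_C, delta_E) {
  if (delta_E == 0) return(list(icer = NA_real_, tag = "undefined"))
  tag <- if (delta_E > 0 && delta_C <= 0) "dominant"
  else if (delta_E < 0 && delta_C >= 0) "dominated"
  else "tradeoff"
  list(icer = delta_C / delta_E, tag = tag)
}

#' Quadrant distribution of a bootstrap cloud on the CE plane
#'
#' Each (delta_E, delta_C) pair is classified by sign: NE = more effective
#' and costlier, SE = more effective and cheaper (dominant), SW = less
#' effective and cheaper, NW = less effective and costlier (dominated).
#' Exact zeros are assigned to the favourable side: a zero incremental
#' effect counts as effective and a zero incremental cost as cost-saving,
#' so (0, negative) falls in SE.
#'
#' @param cloud A `ce_cloud` (or data frame with `delta_C`, `delta_E`, and
#'   optionally `comparison`).
#' @return Data frame per comparison with percentage columns `NE`, `SE`,
#'   `SW`, `NW` summing to 100.
#' @export
ce_plane_distribution <- function(cloud) {
  if (!nrow(cloud)) stop("ce_plane_distribution: empty cloud", call. = FALSE)
  if (is.null(cloud$comparison)) cloud$comparison <- "all"
  parts <- lapply(split(cloud, cloud$comparison), function(d) {
    eff <- d$delta_E >= 0
    cheap <- d$delta_C <= 0
    data.frame(comparison = d$comparison[1],
               NE = 100 * mean(eff & !cheap),
               SE = 100 * mean(eff & cheap),
               SW = 100 * mean(!eff & cheap),
               NW = 100 * mean(!eff & !cheap),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Willingness-to-pay grid
#'
#' @param unit `"qaly"` (default grid 0 to 100 000 EUR by 1000) or `"days"`
#'   (0 to 500 EUR by 10).
#' @param ceiling,step Optional overrides.
#' @return Strictly increasing non-negative numeric vector of lambda values.
#' @export
wtp_grid <- function(unit = c("qaly", "days"), ceiling = NULL, step = NULL) {
  unit <- match.arg(unit)
  if (is.null(ceiling)) ceiling <- if (unit == "qaly") 1e5 else 500
  if (is.null(step)) step <- if (unit == "qaly") 1000 else 10
  if (ceiling <= 0 || step <= 0)
    stop("wtp_grid: ceiling and step must be positive", call. = FALSE)
  seq(0, ceiling, by = step)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value `lambda`, the probability of being
#' cost-effective is the fraction of the bootstrap cloud with positive net
#' monetary benefit `lambda * delta_E - delta_C`.
#'
#' @param cloud A `ce_cloud`.
#' @param grid Lambda values (see [wtp_grid()]).
#' @return Data frame: `comparison`, `lambda`, `p_ce`.
#' @export
ceac <- function(cloud, grid = wtp_grid("days")) {
  if (!nrow(cloud)) stop("ceac: empty cloud", call. = FALSE)
  if (any(diff(grid) <= 0) || any(grid < 0))
    stop("ceac: grid must be non-negative and strictly increasing", call. = FALSE)
  if (is.null(cloud$comparison)) cloud$comparison <- "all"
  parts <- lapply(split(cloud, cloud$comparison), function(d) {
    p <- vapply(grid, function(l) mean(l * d$delta_E - d$delta_C > 0), numeric(1))
    data.frame(comparison = d$comparison[1], lambda = grid, p_ce = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Cost-benefit (return-on-investment) metrics
#'
#' The three point metrics of a cost-benefit analysis: net benefit
#' `NB = benefits - costs`, benefit-cost ratio `BCR = benefits / costs`, and
#' return on investment `ROI = (benefits - costs) / costs x 100` (percent),
#' so `ROI = (BCR - 1) x 100` identically.
#'
#' @param benefits Monetized outcome difference versus control (EUR);
#'   positive values indicate reduced spending.
#' @param costs Intervention costs (EUR).
#' @return List of class `roi_result`: `benefits`, `costs`, `net_benefit`,
#'   `bcr`, `roi` (`bcr`/`roi` are `NA` with tag `"undefined"` when
#'   `costs = 0`).
#' @export
cba_metrics <- function(benefits, costs) {
  if (!is.finite(benefits) || !is.finite(costs))
    stop("cba_metrics: non-finite inputs", call. = FALSE)
  nb <- benefits - costs
  if (costs > 0) {
    bcr <- benefits / costs
    roi <- (benefits - costs) / costs * 100
    tag <- "defined"
  } else {
    bcr <- NA_real_; roi <- NA_real_; tag <- "undefined"
  }
  structure(list(benefits = benefits, costs = costs, net_benefit = nb,
                 bcr = bcr, roi = roi, tag = tag),
            class = "roi_result")
}

#' @export
print.roi_result <- function(x, ...) {
  cat(sprintf("NB = %.1f  BCR = %.2f  ROI = %.1f%%\n",
              x$net_benefit, x$bcr, x$roi))
  invisible(x)
}

#' Probability of a positive return
#'
#' Fraction of bootstrap net-benefit draws that are strictly positive.
#'
#' @param nb_draws Numeric vector of bootstrapped net benefits (>= 100
#'   draws).
#' @return Probability in `[0, 1]`.
#' @export
prob_positive_return <- function(nb_draws) {
  if (length(nb_draws) < 100)
    stop("prob_positive_return: need at least 100 draws", call. = FALSE)
  mean(nb_draws > 0)
}
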