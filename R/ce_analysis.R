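#' Prepare cost and effect columns for a CE or cost-utility analysis
#'
#' For `effect = "days"` (cost-effectiveness on sickness-absence days) the
#' effect is days averted (`-absence_days`) and the cost side excludes
#' absenteeism, which is the monetized effect itself (double counting);
#' intervention, healthcare and unpaid-productivity costs remain. For
#' `effect = "qaly"` (cost-utility) the effect is the participant QALY and
#' the cost side is the total societal cost.
#'
#' @param baseline Cohort baseline table.
#' @param effect `"days"` or `"qaly"`.
#' @param qaly_method QALY construction, see [compute_qaly()].
#' @return `baseline` with columns `ce_cost` and `ce_effect` appended.
#' @export
prepare_ce_columns <- function(baseline, effect = c("days", "qaly"),
                               qaly_method = c("single-point", "auc-linear")) {
  effect <- match.arg(effect)
  if (effect == "days") {
    baseline$ce_cost <- baseline$cost_intervention +
      baseline$cost_healthcare_primary + baseline$cost_healthcare_secondary +
      baseline$cost_unpaid
    baseline$ce_effect <- -baseline$absence_days
  } else {
    baseline$ce_cost <- baseline$cost_total
    baseline$ce_effect <- cohort_qaly(baseline, match.arg(qaly_method))
  }
  baseline
}

#' Full cost-effectiveness / cost-utility analysis
#'
#' Runs the SUR estimator for the incremental cost and effect of each
#' intervention arm versus the reference, a stratified nonparametric
#' bootstrap for their joint uncertainty, and summarizes the cloud as an
#' ICER with dominance tag, the CE-plane quadrant distribution, and a
#' cost-effectiveness acceptability curve. With an imputation stack the SUR
#' estimates are pooled by Rubin's rules and the bootstrap is run within
#' each completed dataset.
#'
#' @param data A complete baseline table or an `imputation_stack` of
#'   baseline tables.
#' @param effect `"days"` or `"qaly"` (see [prepare_ce_columns()]).
#' @param covariates Optional adjustment covariates (both equations).
#' @param B Bootstrap replicates.
#' @param seed Seed for the bootstrap stage.
#' @param wtp Willingness-to-pay grid; defaults to the unit-appropriate
#'   [wtp_grid()].
#' @param qaly_method QALY construction.
#' @param conf Confidence level for the percentile intervals.
#' @return Object of class `ce_result`: `summary` (per comparison:
#'   `delta_C`, CI, `delta_E`, CI, `icer`, `tag`, quadrant percentages),
#'   `ceac`, `cloud`, `effect`, `B`.
#' @export
ce_analysis <- function(data, effect = c("days", "qaly"), covariates = NULL,
                        B = 2000, seed = 1, wtp = NULL,
                        qaly_method = c("single-point", "auc-linear"),
                        conf = 0.95) {
  effect <- match.arg(effect)
  qaly_method <- match.arg(qaly_method)
  if (is.null(wtp)) wtp <- wtp_grid(if (effect == "days") "days" else "qaly")
  is_stack <- inherits(data, "imputation_stack")
  if (is_stack) {
    prepped <- data
    prepped$datasets <- lapply(data$datasets, prepare_ce_columns,
                               effect = effect, qaly_method = qaly_method)
    fits <- lapply(prepped$datasets, sur_fit, cost_col = "ce_cost",
                   effect_col = "ce_effect", covariates_cost = covariates)
    comps <- fits[[1]]$delta$comparison
    point <- do.call(rbind, lapply(seq_along(comps), function(i) {
      pc <- rubin_pool(vapply(fits, function(f) f$delta$delta_C[i], numeric(1)),
                       vapply(fits, function(f) f$delta$se_C[i]^2, numeric(1)))
      pe <- rubin_pool(vapply(fits, function(f) f$delta$delta_E[i], numeric(1)),
                       vapply(fits, function(f) f$delta$se_E[i]^2, numeric(1)))
      data.frame(comparison = comps[i], delta_C = pc$estimate,
                 delta_E = pe$estimate, stringsAsFactors = FALSE)
    }))
    cloud <- bootstrap_ce(prepped, "ce_cost", "ce_effect",
                          covariates_cost = covariates, B = B, seed = seed)
  } else {
    d <- prepare_ce_columns(data, effect, qaly_method)
    fit <- sur_fit(d, "ce_cost", "ce_effect", covariates_cost = covariates)
    point <- fit$delta[, c("comparison", "delta_C", "delta_E")]
    cloud <- bootstrap_ce(d, "ce_cost", "ce_effect",
                          covariates_cost = covariates, B = B, seed = seed)
  }
  quad <- ce_plane_distribution(cloud)
  al <- (1 - conf) / 2
  rows <- lapply(seq_len(nrow(point)), function(i) {
    cc <- cloud[cloud$comparison == point$comparison[i], ]
    ic <- icer(point$delta_C[i], point$delta_E[i])
    data.frame(point[i, ],
               lcl_C = stats::quantile(cc$delta_C, al, names = FALSE),
               ucl_C = stats::quantile(cc$delta_C, 1 - al, names = FALSE),
               lcl_E = stats::quantile(cc$delta_E, al, names = FALSE),
               ucl_E = stats::quantile(cc$delta_E, 1 - al, names = FALSE),
               icer = ic$icer, tag = ic$tag, stringsAsFactors = FALSE)
  })
  summary <- merge(do.call(rbind, rows), quad, by = "comparison", sort = FALSE)
  structure(list(summary = summary, ceac = ceac(cloud, wtp), cloud = cloud,
                 effect = effect, B = B, seed = seed),
            class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat("Cost-", if (x$effect == "qaly") "utility" else "effectiveness",
      " analysis (effect = ", x$effect, "), B = ", x$B, "\n", sep = "")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Cost-benefit / return-on-investment analysis
#'
#' Costs are the incremental intervention costs of each intervention arm
#' versus the reference; benefits are the monetized outcome reductions
#' (absenteeism, unpaid productivity losses and healthcare spending), with
#' positive benefits indicating reduced spending. Point metrics follow
#' [cba_metrics()]; uncertainty comes from the same stratified bootstrap as
#' the CE analysis, and the probability of a positive return is the
#' fraction of bootstrap net-benefit draws above zero.
#'
#' @param data Complete baseline table or an `imputation_stack`.
#' @param B Bootstrap replicates.
#' @param seed Bootstrap seed.
#' @param conf Confidence level for percentile intervals.
#' @return Object of class `roi_analysis`: per-comparison data frame with
#'   `costs`, `benefits`, `net_benefit` (each with CI), `bcr`, `roi`,
#'   `prob_positive_return`; plus the draw table.
#' @export
roi_analysis <- function(data, B = 2000, seed = 1, conf = 0.95) {
  is_stack <- inherits(data, "imputation_stack")
  datasets <- if (is_stack) data$datasets else list(data)
  Bm <- ceiling(B / length(datasets))
  point <- roi_point(datasets[[1]])
  if (is_stack) {
    pts <- lapply(datasets, roi_point)
    for (j in c("costs", "benefits"))
      point[[j]] <- rowMeans(do.call(cbind, lapply(pts, `[[`, j)))
  }
  set.seed(seed)
  draws <- list()
  for (d in datasets) {
    for (b in seq_len(Bm)) {
      db <- d[stratified_resample(d$arm), ]
      draws[[length(draws) + 1L]] <- roi_point(db)
    }
  }
  drawdf <- do.call(rbind, draws)
  al <- (1 - conf) / 2
  rows <- lapply(unique(point$comparison), function(cmp) {
    p <- point[point$comparison == cmp, ]
    dd <- drawdf[drawdf$comparison == cmp, ]
    nb <- dd$benefits - dd$costs
    m <- cba_metrics(p$benefits, p$costs)
    data.frame(comparison = cmp,
               costs = p$costs,
               costs_lcl = stats::quantile(dd$costs, al, names = FALSE),
               costs_ucl = stats::quantile(dd$costs, 1 - al, names = FALSE),
               benefits = p$benefits,
               benefits_lcl = stats::quantile(dd$benefits, al, names = FALSE),
               benefits_ucl = stats::quantile(dd$benefits, 1 - al, names = FALSE),
               net_benefit = m$net_benefit,
               nb_lcl = stats::quantile(nb, al, names = FALSE),
               nb_ucl = stats::quantile(nb, 1 - al, names = FALSE),
               bcr = m$bcr, roi = m$roi,
               prob_positive_return = prob_positive_return(nb),
               stringsAsFactors = FALSE)
  })
  structure(list(summary = do.call(rbind, rows), draws = drawdf,
                 B = Bm * length(datasets), seed = seed),
            class = "roi_analysis")
}

# incremental intervention costs and monetized benefits vs the reference arm
roi_point <- function(d) {
  d$arm <- droplevels(factor(d$arm))
  ref <- levels(d$arm)[1]
  spend <- d$cost_absenteeism + d$cost_unpaid +
    d$cost_healthcare_primary + d$cost_healthcare_secondary
  out <- lapply(levels(d$arm)[-1], function(a) {
    ia <- d$arm == a; ir <- d$arm == ref
    data.frame(comparison = paste(a, "vs", ref),
               costs = mean(d$cost_intervention[ia]) - mean(d$cost_intervention[ir]),
               benefits = mean(spend[ir]) - mean(spend[ia]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.roi_analysis <- function(x, ...) {
  cat("Return-on-investment analysis, B =", x$B, "\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
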