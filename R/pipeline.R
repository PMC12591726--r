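#' Run the six effectiveness analyses on a cohort
#'
#' Sickness-absence days (Mann-Whitney and robust regression, unadjusted and
#' adjusted), time to sustained RTW (Kaplan-Meier, log-rank, Cox), monthly
#' benefit receipt (clustered person-month logit), and repeated
#' musculoskeletal-health scores (linear mixed model). Adjusted models use
#' complete cases of the covariate set.
#'
#' @param cohort A `trial_cohort`.
#' @param covariates Adjustment set (default [default_adjustment_set()]).
#' @return List with `absence_days` (effect estimates), `mann_whitney`,
#'   `km` (per-arm survival), `log_rank`, `cox`, `benefit_or`, `mskhq`,
#'   and `tidy` (all effect estimates stacked).
#' @export
run_effectiveness <- function(cohort, covariates = default_adjustment_set()) {
  b <- cohort$baseline
  rtw <- sustained_rtw(cohort)
  rtw <- rtw[match(b$id, rtw$id), ]
  arms <- levels(b$arm)
  ref <- arms[1]

  mw <- do.call(rbind, lapply(arms[-1], function(a) {
    t <- mann_whitney_u(b$absence_days[b$arm == a], b$absence_days[b$arm == ref])
    data.frame(comparison = paste(a, "vs", ref), U = t$U, p_value = t$p_value,
               method = t$method, stringsAsFactors = FALSE)
  }))

  days_u <- robust_linear_diff(b)
  days_a <- robust_linear_diff(b, covariates = covariates)
  km <- kaplan_meier(rtw, group = b$arm)
  lr <- log_rank(rtw, b$arm)
  cox_u <- cox_ph(rtw, b, covariates = NULL)
  cox_a <- cox_ph(rtw, b, covariates = covariates)
  or_u <- monthly_benefit_model(cohort$panel, b)
  or_a <- monthly_benefit_model(cohort$panel, b, covariates = covariates)
  msk <- mskhq_mixed_model(b)

  tidy <- rbind(
    cbind(outcome = "absence_days", days_u[, names(days_u) != "month"]),
    cbind(outcome = "absence_days", days_a),
    cbind(outcome = "sustained_rtw", cox_u),
    cbind(outcome = "sustained_rtw", cox_a),
    cbind(outcome = "monthly_benefit", or_u),
    cbind(outcome = "monthly_benefit", or_a),
    cbind(outcome = "mskhq", msk[, names(msk) != "month"]))
  list(absence_days = rbind(days_u, days_a), mann_whitney = mw, km = km,
       log_rank = lr, cox = rbind(cox_u, cox_a),
       benefit_or = rbind(or_u, or_a), mskhq = msk, tidy = tidy)
}

#' Run the full simulate-impute-analyze-evaluate pipeline
#'
#' Executes every stage on a configured synthetic trial, persists all
#' intermediates as plain CSV/JSON under `out_dir` (so each stage is
#' individually re-runnable and testable), and writes a run manifest with
#' the config checksum, the master seed, per-stage runtimes and the file
#' inventory. Identical config and seed reproduce identical outputs.
#'
#' @param config A [cohort_config()] or the path of a YAML config.
#' @param out_dir Output directory.
#' @param B Bootstrap replicates for the economic evaluation.
#' @param M Imputed datasets (when the cohort has missing values).
#' @param qaly_method QALY construction for the cost-utility analysis.
#' @param covariates Adjustment set.
#' @return The run manifest (list), invisibly; outputs land in `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, B = 2000, M = 10,
                         qaly_method = c("single-point", "auc-linear"),
                         covariates = default_adjustment_set()) {
  qaly_method <- match.arg(qaly_method)
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "cohort_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  runtimes <- list()
  tick <- function(expr, stage) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
    runtimes[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    r
  }

  cohort <- tick({
    co <- generate_cohort(config)
    co <- impose_missingness(co)
    write_cohort(co, file.path(out_dir, "cohort"))
    co
  }, "simulate")

  stack <- tick({
    vars <- names(cohort$baseline)[vapply(cohort$baseline, anyNA, logical(1))]
    st <- if (length(vars))
      mice_pmm(cohort$baseline, variables = vars, M = M,
               seed = stage_seed(config$seed, "impute"))
    else mice_pmm(rbind(cohort$baseline), M = max(M, 2),
                  seed = stage_seed(config$seed, "impute"))
    write_stack(st, file.path(out_dir, "imputed"))
    st
  }, "impute")

  eff <- tick({
    e <- run_effectiveness(cohort, covariates)
    utils::write.csv(e$tidy, file.path(out_dir, "effectiveness.csv"),
                     row.names = FALSE)
    utils::write.csv(e$km, file.path(out_dir, "km_survival.csv"),
                     row.names = FALSE)
    utils::write.csv(e$mann_whitney, file.path(out_dir, "mann_whitney.csv"),
                     row.names = FALSE)
    e
  }, "analyze")

  tick({
    bseed <- stage_seed(config$seed, "bootstrap")
    ce_days <- ce_analysis(stack, effect = "days", B = B, seed = bseed)
    ce_qaly <- ce_analysis(stack, effect = "qaly", B = B, seed = bseed + 1L,
                           qaly_method = qaly_method)
    roi <- roi_analysis(stack, B = B, seed = bseed + 2L)
    cost_tab <- cost_difference_table(completed(stack, 1), covariates,
                                      B = min(B, 1000), seed = bseed + 3L)
    utils::write.csv(rbind(cbind(effect = "days", ce_days$summary),
                           cbind(effect = "qaly", ce_qaly$summary)),
                     file.path(out_dir, "ce_summary.csv"), row.names = FALSE)
    utils::write.csv(rbind(cbind(effect = "days", ce_days$ceac),
                           cbind(effect = "qaly", ce_qaly$ceac)),
                     file.path(out_dir, "ceac.csv"), row.names = FALSE)
    utils::write.csv(ce_days$cloud, file.path(out_dir, "ce_cloud_days.csv"),
                     row.names = FALSE)
    utils::write.csv(roi$summary, file.path(out_dir, "roi.csv"),
                     row.names = FALSE)
    utils::write.csv(cost_tab, file.path(out_dir, "cost_table.csv"),
                     row.names = FALSE)
  }, "evaluate")

  manifest <- list(
    config_md5 = unname(tools::md5sum(file.path(out_dir, "cohort", "config.yaml"))),
    seed = config$seed, B = B, M = M, qaly_method = qaly_method,
    package_version = as.character(utils::packageVersion("trialecon")),
    runtimes = runtimes,
    files = sort(list.files(out_dir, recursive = TRUE)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Render the four result tables of a pipeline run
#'
#' Reads the persisted CSVs under a results directory and formats the
#' survival table, the cost table, the cost-effectiveness table and the
#' return-on-investment table as plain text. Sections whose inputs are
#' missing are flagged as gaps rather than failing.
#'
#' @param results_dir Directory written by [run_pipeline()].
#' @param file Optional path to also write the report to.
#' @return Character vector of report lines, invisibly printed.
#' @export
render_tables <- function(results_dir, file = NULL) {
  out <- c("Synthetic trial: 12-month effectiveness and economic evaluation",
           strrep("=", 64))
  grab <- function(name) {
    p <- file.path(results_dir, name)
    if (file.exists(p)) utils::read.csv(p, stringsAsFactors = FALSE) else NULL
  }
  fmt <- function(d) c(utils::capture.output(print(d, row.names = FALSE,
                                                   digits = 3)), "")
  km <- grab("km_survival.csv")
  out <- c(out, "", "Table A - Probability of no sustained RTW by month")
  out <- c(out, if (is.null(km)) "  [missing: km_survival.csv]" else {
    wide <- stats::reshape(km[, c("group", "month", "surv")],
                           direction = "wide", idvar = "month",
                           timevar = "group")
    fmt(wide[order(wide$month), ])
  })
  ct <- grab("cost_table.csv")
  out <- c(out, "Table B - Mean costs per participant and differences (EUR)")
  out <- c(out, if (is.null(ct)) "  [missing: cost_table.csv]"
           else fmt(ct[, c("component", "comparison", "mean_ref", "mean_arm",
                           "diff_unadj", "lcl_unadj", "ucl_unadj")]))
  ce <- grab("ce_summary.csv")
  out <- c(out, "Table C - Cost-effectiveness and cost-utility")
  out <- c(out, if (is.null(ce)) "  [missing: ce_summary.csv]"
           else fmt(ce[, c("effect", "comparison", "delta_C", "lcl_C", "ucl_C",
                           "delta_E", "lcl_E", "ucl_E", "icer", "tag",
                           "NE", "SE", "SW", "NW")]))
  roi <- grab("roi.csv")
  out <- c(out, "Table D - Return on investment")
  out <- c(out, if (is.null(roi)) "  [missing: roi.csv]"
           else fmt(roi[, c("comparison", "costs", "benefits", "net_benefit",
                            "nb_lcl", "nb_ucl", "bcr", "roi",
                            "prob_positive_return")]))
  if (!is.null(file)) writeLines(out, file)
  invisible(out)
}
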