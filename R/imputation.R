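#' Multiple imputation by chained equations with predictive mean matching
#'
#' Cycles a chained-equations Gibbs-style sampler over the variables with
#' missing values. Each variable is regressed on the other analysis
#' variables (current completed values); every missing entry is then
#' replaced by the *observed* value of a donor drawn at random from the
#' `donors` cases whose predicted means are closest to the predicted mean of
#' the missing case (predictive mean matching). With `match_type = 1`
#' (default) the predictions for the missing cases use a regression
#' coefficient vector drawn from its approximate posterior, which propagates
#' parameter uncertainty between imputations; `match_type = 0` uses the
#' least-squares estimate for both sides and is fully deterministic given
#' the donor set.
#'
#' Categorical and logical variables are imputed via PMM on a linear score
#' of their numeric coding; because donors return observed values, imputed
#' entries are always members of the observed support and types are
#' preserved.
#'
#' @param data A data frame (e.g. a cohort baseline table).
#' @param variables Columns to impute; default all columns with missing
#'   values.
#' @param predictors Columns used as regressors; default every column except
#'   `id` and constant columns.
#' @param M Number of completed datasets (>= 2, default 10).
#' @param iterations Chained-equation cycles per dataset (default 10).
#' @param donors Size of the donor pool (default 5).
#' @param seed Seed; the sampler is deterministic given it.
#' @param match_type 0 or 1, see above.
#' @return An object of class `imputation_stack`: `M`, `datasets` (list of
#'   completed data frames), `variables`, `iterations`, `donors`, `seed`,
#'   and `chain_means` (per-dataset trace of imputed-value means).
#' @export
mice_pmm <- function(data, variables = NULL, predictors = NULL,
                     M = 10, iterations = 10, donors = 5, seed = 1,
                     match_type = 1) {
  stopifnot(is.data.frame(data), M >= 2, iterations >= 1, donors >= 1)
  if (is.null(variables))
    variables <- names(data)[vapply(data, anyNA, logical(1))]
  if (is.null(predictors)) {
    nonconst <- vapply(data, function(x) length(unique(x[!is.na(x)])) > 1, logical(1))
    complete_col <- !vapply(data, anyNA, logical(1))
    predictors <- setdiff(names(data)[nonconst & (complete_col |
                                                    names(data) %in% variables)],
                          "id")
  }
  predictors <- union(predictors, variables)
  for (v in variables) {
    obs <- sum(!is.na(data[[v]]))
    if (obs == 0)
      stop("mice_pmm: variable '", v, "' has no observed values", call. = FALSE)
    if (donors > obs)
      stop("mice_pmm: donors (", donors, ") exceeds observed count (", obs,
           ") for '", v, "'", call. = FALSE)
  }
  miss_idx <- lapply(data[variables], function(x) which(is.na(x)))
  if (!any(lengths(miss_idx) > 0)) {
    datasets <- replicate(M, data, simplify = FALSE)
    return(structure(list(M = M, datasets = datasets, variables = variables,
                          iterations = iterations, donors = donors, seed = seed,
                          chain_means = NULL),
                     class = "imputation_stack"))
  }
  set.seed(seed)
  datasets <- vector("list", M)
  traces <- list()
  for (m in seq_len(M)) {
    d <- data
    # initialize missing entries from random observed draws
    for (v in variables) {
      ix <- miss_idx[[v]]
      if (!length(ix)) next
      pool <- d[[v]][!is.na(d[[v]])]
      d[[v]][ix] <- sample(pool, length(ix), replace = TRUE)
    }
    for (it in seq_len(iterations)) {
      for (v in variables) {
        ix <- miss_idx[[v]]
        if (!length(ix)) next
        d[[v]][ix] <- pmm_draw(d, v, ix, setdiff(predictors, v),
                               donors, match_type, is.na(data[[v]]))
        traces[[length(traces) + 1L]] <- data.frame(
          dataset = m, iteration = it, variable = v,
          imputed_mean = mean(as_numeric_code(d[[v]][ix])))
      }
    }
    datasets[[m]] <- d
  }
  structure(list(M = M, datasets = datasets, variables = variables,
                 iterations = iterations, donors = donors, seed = seed,
                 chain_means = do.call(rbind, traces)),
            class = "imputation_stack")
}

# one PMM update for variable v at rows ix
pmm_draw <- function(d, v, ix, preds, donors, match_type, orig_na) {
  yfull <- as_numeric_code(d[[v]])
  X <- stats::model.matrix(stats::reformulate(preds),
                           data = d[, preds, drop = FALSE])
  obs <- which(!orig_na)
  yo <- yfull[obs]
  Xo <- X[obs, , drop = FALSE]
  Xm <- X[ix, , drop = FALSE]
  XtX <- crossprod(Xo)
  ridge <- diag(ncol(XtX)) * 1e-8 * mean(diag(XtX))
  XtXi <- solve(XtX + ridge)
  beta <- XtXi %*% crossprod(Xo, yo)
  yhat_obs <- drop(Xo %*% beta)
  if (match_type == 1) {
    df <- max(length(obs) - ncol(Xo), 1)
    rss <- sum((yo - yhat_obs)^2)
    sigma2 <- rss / stats::rchisq(1, df)
    cholV <- tryCatch(chol(XtXi * sigma2), error = function(e) NULL)
    beta_star <- if (is.null(cholV)) beta
    else beta + t(cholV) %*% stats::rnorm(ncol(Xo))
    yhat_mis <- drop(Xm %*% beta_star)
  } else {
    yhat_mis <- drop(Xm %*% beta)
  }
  out <- d[[v]][ix]
  for (j in seq_along(ix)) {
    dist <- abs(yhat_obs - yhat_mis[j])
    pool <- obs[order(dist)][seq_len(donors)]
    out[j] <- d[[v]][pool[sample.int(donors, 1L)]]
  }
  out
}

as_numeric_code <- function(x) {
  if (is.numeric(x)) x
  else if (is.logical(x)) as.numeric(x)
  else as.numeric(factor(x))
}

#' Extract one completed dataset from an imputation stack
#'
#' @param stack An `imputation_stack`.
#' @param i Dataset index in `1..M`.
#' @return A completed data frame.
#' @export
completed <- function(stack, i) {
  stopifnot(inherits(stack, "imputation_stack"), i >= 1, i <= stack$M)
  stack$datasets[[i]]
}

#' @export
print.imputation_stack <- function(x, ...) {
  cat("Imputation stack: M =", x$M, "completed datasets;",
      length(x$variables), "imputed variable(s);",
      x$iterations, "iterations; donors =", x$donors, "\n")
  invisible(x)
}

#' Pool estimates across imputed datasets by Rubin's rules
#'
#' The pooled point estimate is the mean of the per-dataset estimates; the
#' total variance decomposes as within-imputation variance plus
#' `(1 + 1/M)` times the between-imputation variance. Confidence intervals
#' use a t reference with Barnard-Rubin adjusted degrees of freedom (the
#' classical large-sample degrees of freedom when `df_complete = Inf`).
#'
#' @param estimates Numeric vector of per-dataset point estimates (M >= 2).
#' @param variances Numeric vector of per-dataset squared standard errors.
#' @param df_complete Complete-data residual degrees of freedom (default
#'   `Inf`).
#' @param conf Confidence level.
#' @return A list of class `pooled_estimate`: `estimate`, `within`,
#'   `between`, `total_variance`, `df`, `lcl`, `ucl`, `M`.
#' @export
rubin_pool <- function(estimates, variances, df_complete = Inf, conf = 0.95) {
  M <- length(estimates)
  if (M < 2) stop("rubin_pool: need at least 2 imputed estimates", call. = FALSE)
  if (length(variances) != M)
    stop("rubin_pool: 'estimates' and 'variances' differ in length", call. = FALSE)
  qbar <- mean(estimates)
  W <- mean(variances)
  B <- stats::var(estimates)
  Tt <- W + (1 + 1 / M) * B
  if (B > 0 && Tt > 0) {
    lambda <- (1 + 1 / M) * B / Tt
    nu_old <- (M - 1) / lambda^2
    nu <- if (is.finite(df_complete)) {
      nu_obs <- (df_complete + 1) / (df_complete + 3) * df_complete * (1 - lambda)
      1 / (1 / nu_old + 1 / nu_obs)
    } else nu_old
  } else nu <- Inf
  tq <- stats::qt((1 + conf) / 2, df = nu)
  structure(list(estimate = qbar, within = W, between = B,
                 total_variance = Tt, df = nu,
                 lcl = qbar - tq * sqrt(Tt), ucl = qbar + tq * sqrt(Tt),
                 M = M),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("Pooled estimate %.4g (95%% CI %.4g to %.4g); T = W + (1+1/M)B = %.4g + %.4g\n",
              x$estimate, x$lcl, x$ucl, x$within, (1 + 1 / x$M) * x$between))
  invisible(x)
}

#' Persist / load an imputation stack as CSVs plus a JSON manifest
#'
#' One CSV per completed dataset (`imputed_<i>.csv`) and a `manifest.json`
#' recording `M`, `seed`, `iterations`, `donors` and the imputed variables.
#'
#' @param stack An `imputation_stack`.
#' @param dir Directory (created if absent).
#' @return `write_stack()` returns `dir` invisibly; `read_stack()` returns an
#'   `imputation_stack`.
#' @export
write_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "imputation_stack"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_len(stack$M))
    utils::write.csv(stack$datasets[[i]],
                     file.path(dir, sprintf("imputed_%02d.csv", i)),
                     row.names = FALSE)
  manifest <- list(M = stack$M, seed = stack$seed,
                   iterations = stack$iterations, donors = stack$donors,
                   variables = stack$variables)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_stack
#' @export
read_stack <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  datasets <- lapply(seq_len(manifest$M), function(i)
    utils::read.csv(file.path(dir, sprintf("imputed_%02d.csv", i)),
                    stringsAsFactors = FALSE))
  structure(list(M = manifest$M, datasets = datasets,
                 variables = manifest$variables,
                 iterations = manifest$iterations, donors = manifest$donors,
                 seed = manifest$seed, chain_means = NULL),
            class = "imputation_stack")
}
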