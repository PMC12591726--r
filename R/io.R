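#' Write / read a cohort as plain CSV files
#'
#' The baseline table is written wide (one row per participant) to
#' `baseline.csv`, the monthly panel long (`id`, `month`, `absence_fraction`,
#' `benefit_received`) to `panel.csv`, and the generator configuration to
#' `config.yaml`. Absent values are empty fields. Numeric values are written
#' with 17 significant digits so a round trip reproduces the cohort exactly.
#'
#' `read_cohort()` validates the invariants of the schema - absence
#' fractions within `[0, 1]`, musculoskeletal-health scores within
#' `[0, 56]`, cost components non-negative - and rejects a malformed file
#' citing the offending row.
#'
#' @param cohort A `trial_cohort`.
#' @param dir Directory (created if absent).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` a
#'   `trial_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "trial_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_csv_exact(cohort$baseline, file.path(dir, "baseline.csv"))
  write_csv_exact(cohort$panel, file.path(dir, "panel.csv"))
  write_config(cohort$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

# CSV writer preserving doubles to 17 significant digits
write_csv_exact <- function(d, path) {
  d2 <- d
  for (j in seq_along(d2)) {
    if (is.double(d2[[j]])) {
      x <- vapply(d2[[j]], function(v)
        if (is.na(v)) NA_character_ else sprintf("%.17g", v), character(1))
      # drop trailing noise on integers-in-double
      d2[[j]] <- sub("\\.0+$", "", x)
    }
  }
  utils::write.csv(d2, path, row.names = FALSE, na = "")
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  bpath <- file.path(dir, "baseline.csv")
  ppath <- file.path(dir, "panel.csv")
  if (!file.exists(bpath) || !file.exists(ppath))
    stop("read_cohort: expected baseline.csv and panel.csv under ", dir,
         call. = FALSE)
  baseline <- utils::read.csv(bpath, stringsAsFactors = FALSE, na.strings = "")
  panel <- utils::read.csv(ppath, stringsAsFactors = FALSE, na.strings = "")
  config <- if (file.exists(file.path(dir, "config.yaml")))
    read_config(file.path(dir, "config.yaml")) else NULL
  validate_baseline(baseline)
  validate_panel(panel)
  if (nrow(baseline)) {
    lev <- if (!is.null(config))
      vapply(config$arms, `[[`, character(1), "label") else unique(baseline$arm)
    baseline$arm <- factor(baseline$arm, levels = lev)
    if ("benefit_received" %in% names(panel))
      panel$benefit_received <- as.logical(panel$benefit_received)
  }
  structure(list(baseline = baseline, panel = panel, config = config),
            class = "trial_cohort")
}

validate_panel <- function(panel) {
  need <- c("id", "month", "absence_fraction")
  miss <- setdiff(need, names(panel))
  if (length(miss))
    stop("read_cohort: panel.csv lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(!is.na(panel$absence_fraction) &
                 (panel$absence_fraction < 0 | panel$absence_fraction > 1))
  if (length(bad))
    stop("read_cohort: absence_fraction outside [0, 1] at panel.csv row ",
         bad[1] + 1L, " (value ", panel$absence_fraction[bad[1]], ")",
         call. = FALSE)
  invisible(panel)
}

validate_baseline <- function(b) {
  if (!nrow(b)) return(invisible(b))
  for (col in grep("^mskhq_", names(b), value = TRUE)) {
    bad <- which(!is.na(b[[col]]) & (b[[col]] < 0 | b[[col]] > 56))
    if (length(bad))
      stop("read_cohort: ", col, " outside [0, 56] at baseline.csv row ",
           bad[1] + 1L, call. = FALSE)
  }
  for (col in intersect(c(cost_components, "cost_total"), names(b))) {
    bad <- which(!is.na(b[[col]]) & b[[col]] < 0)
    if (length(bad))
      stop("read_cohort: negative ", col, " at baseline.csv row ", bad[1] + 1L,
           call. = FALSE)
  }
  invisible(b)
}
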