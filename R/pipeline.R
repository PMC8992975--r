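#' Validate study input tables
#'
#' Checks the carcass, trial, and (optionally) operations tables before
#' estimation: required columns, duplicate carcass identifiers,
#' distances beyond the plot corner not flagged as off-plot, and
#' logical consistency of trial outcomes.  Off-plot carcasses are
#' retained in the returned table but flagged; estimation excludes them
#' and reports the count.
#'
#' @param data A named list with elements `carcasses`, `seef_trials`,
#'   `persistence_trials`, and optionally `ops`.
#' @param plot A [square_plot()].
#' @return The validated list, with a `warnings` character attribute.
#' @export
validate_study_data <- function(data, plot = square_plot()) {
  warnings <- character()
  tau <- plot$truncation_distance

  cc <- tibble::as_tibble(data$carcasses)
  req <- c("carcass_id", "turbine_id", "treatment", "distance_m")
  missing_cols <- setdiff(req, names(cc))
  if (length(missing_cols)) {
    abort(paste("carcasses: missing column(s):",
                paste(missing_cols, collapse = ", ")),
          class = "curtailr_validation_error")
  }
  if (!"inside_plot" %in% names(cc)) cc$inside_plot <- TRUE
  dup <- duplicated(cc$carcass_id)
  if (any(dup)) {
    abort(sprintf("carcasses: duplicate carcass_id in row(s) %s.",
                  paste(which(dup), collapse = ", ")),
          class = "curtailr_validation_error")
  }
  bad_d <- which(!is.finite(cc$distance_m) | cc$distance_m < 0)
  if (length(bad_d)) {
    abort(sprintf("carcasses: invalid distance in row(s) %s.",
                  paste(bad_d, collapse = ", ")),
          class = "curtailr_validation_error")
  }
  too_far <- which(cc$distance_m >= tau & cc$inside_plot)
  if (length(too_far)) {
    abort(sprintf(
      "carcasses: row(s) %s at or beyond the corner distance (%.1f m) but flagged inside_plot.",
      paste(too_far, collapse = ", "), tau
    ), class = "curtailr_validation_error")
  }
  n_off <- sum(!cc$inside_plot)
  if (n_off > 0) {
    warnings <- c(warnings, sprintf(
      "%d off-plot carcass(es) flagged; excluded from estimation.", n_off
    ))
  }

  st <- tibble::as_tibble(data$seef_trials)
  if (!all(c("available", "found") %in% names(st))) {
    abort("seef_trials: need `available` and `found` columns.",
          class = "curtailr_validation_error")
  }
  if (any(st$found & !st$available)) {
    abort("seef_trials: found carcasses must be available.",
          class = "curtailr_validation_error")
  }

  pt <- tibble::as_tibble(data$persistence_trials)
  if (!all(c("last_present_d", "first_absent_d") %in% names(pt))) {
    abort("persistence_trials: need `last_present_d` and `first_absent_d`.",
          class = "curtailr_validation_error")
  }
  cens <- if ("censored" %in% names(pt)) pt$censored else is.na(pt$first_absent_d)
  bad <- which(!cens & (is.na(pt$first_absent_d) |
                          pt$last_present_d >= pt$first_absent_d))
  if (length(bad)) {
    abort(sprintf("persistence_trials: invalid interval in row(s) %s.",
                  paste(bad, collapse = ", ")),
          class = "curtailr_validation_error")
  }

  out <- list(carcasses = cc, seef_trials = st, persistence_trials = pt)
  if (!is.null(data$ops)) out$ops <- tibble::as_tibble(data$ops)
  attr(out, "warnings") <- warnings
  out
}

#' Run the full fatality and economics pipeline
#'
#' Orchestrates the complete analysis on a validated study data set:
#' searcher efficiency, persistence model selection, per-treatment
#' distance fitting with pooling fallback, area corrections with
#' bootstrap CIs, detection-adjusted fatality estimates with paired
#' bootstrap CIs and treatment comparisons, and (when operation records
#' are supplied) curtailment, energy and revenue summaries with
#' treatment-difference losses.  Deterministic given `seed`.
#'
#' @param data A list with `carcasses`, `seef_trials`,
#'   `persistence_trials`, and optionally `ops` (see
#'   [validate_study_data()]), or a `sim_study` from
#'   [simulate_study()].
#' @inheritParams estimate_study_fatalities
#' @param price_per_mwh Market revenue rate for the economics stage.
#' @return An object of class `study_report`: the `fatality_study`
#'   object plus `ops_summary`, `ops_comparisons`, the accumulated
#'   `warnings`, and provenance (`seed`, `ci_level`, `k`).
#' @export
run_pipeline <- function(data,
                         plot = square_plot(),
                         k = 0.67,
                         control = "control",
                         pool = NULL,
                         n_turbines = 10,
                         capacity_mw = 1.65,
                         n_boot = 1000,
                         ci_level = 0.90,
                         seed = 1,
                         n_searches = 78,
                         price_per_mwh = 40) {
  if (inherits(data, "sim_study")) {
    data <- list(carcasses = data$carcasses,
                 seef_trials = data$seef_trials,
                 persistence_trials = data$persistence_trials,
                 ops = data$ops)
  }
  data <- validate_study_data(data, plot)
  warnings <- attr(data, "warnings")

  study <- estimate_study_fatalities(
    data$carcasses, data$seef_trials, data$persistence_trials,
    plot = plot, k = k, control = control, pool = pool,
    n_turbines = n_turbines, capacity_mw = capacity_mw,
    n_boot = n_boot, ci_level = ci_level, seed = seed,
    n_searches = n_searches
  )

  ops_summary <- NULL
  ops_comparisons <- NULL
  if (!is.null(data$ops)) {
    ops_summary <- summarize_ops(data$ops, price_per_mwh = price_per_mwh)
    ops_comparisons <- compare_ops(ops_summary, control = control,
                                   price_per_mwh = price_per_mwh)
  }

  structure(
    c(unclass(study),
      list(ops_summary = ops_summary, ops_comparisons = ops_comparisons,
           price_per_mwh = price_per_mwh,
           warnings = c(warnings, study$warnings))),
    class = c("study_report", "fatality_study")
  )
}

#' @export
print.study_report <- function(x, ...) {
  NextMethod()
  if (!is.null(x$ops_summary)) {
    cat("Operations summary:\n")
    print(x$ops_summary)
    print(x$ops_comparisons)
  }
  invisible(x)
}
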