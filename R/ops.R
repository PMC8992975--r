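#' Summarise turbine operations by treatment
#'
#' Aggregates 10-minute turbine operation records into per-treatment
#' summaries: mean wind speed and curtailed fraction over the nightly
#' treatment window, and total energy and revenue per turbine over the
#' whole record.  Revenue is energy times the flat market price.
#'
#' @param records Data frame of 10-minute bins with columns
#'   `turbine_id`, `treatment`, `wind_speed_mps`, logical
#'   `in_treatment_window`, logical `curtailed`, `energy_mwh`.
#' @param price_per_mwh Gross market revenue rate in dollars per MWh
#'   (default 40).
#' @return A tibble with one row per treatment: `treatment`,
#'   `n_turbines`, `mean_wind_mps`, `curtailed_fraction`,
#'   `energy_mwh_per_turbine`, `revenue_per_turbine`.
#' @examples
#' records <- tibble::tibble(
#'   turbine_id = "T1", treatment = "control",
#'   wind_speed_mps = c(4, 6, 8), in_treatment_window = TRUE,
#'   curtailed = FALSE, energy_mwh = c(0.01, 0.05, 0.12)
#' )
#' summarize_ops(records)
#' @export
summarize_ops <- function(records, price_per_mwh = 40) {
  req <- c("turbine_id", "treatment", "wind_speed_mps",
           "in_treatment_window", "curtailed", "energy_mwh")
  if (!all(req %in% names(records))) {
    abort(paste("`records` must have columns:", paste(req, collapse = ", ")),
          class = "curtailr_data_error")
  }
  if (!any(records$in_treatment_window)) {
    abort("No in-window records; nothing to summarise.",
          class = "curtailr_data_error")
  }
  records |>
    dplyr::group_by(.data$treatment) |>
    dplyr::summarise(
      n_turbines = dplyr::n_distinct(.data$turbine_id),
      mean_wind_mps = mean(.data$wind_speed_mps[.data$in_treatment_window]),
      curtailed_fraction =
        mean(.data$curtailed[.data$in_treatment_window]),
      energy_mwh_per_turbine = sum(.data$energy_mwh) / .data$n_turbines,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      revenue_per_turbine = .data$energy_mwh_per_turbine * price_per_mwh
    )
}

#' Energy and revenue loss of one treatment relative to another
#'
#' Lost generation is estimated as the difference in per-turbine energy
#' between a reference group (typically control) and a curtailed group,
#' assuming the groups would have generated similarly absent treatment.
#'
#' @param summaries A [summarize_ops()] tibble.
#' @param ref,alt Treatment labels to compare (`ref` minus `alt`).
#' @param price_per_mwh Price used for the revenue difference; defaults
#'   to the implied price of the summaries.
#' @return A one-row tibble: `comparison`, `energy_difference_mwh`,
#'   `revenue_difference`, `percent_loss` (share of the reference
#'   group's energy, in percent).
#' @export
compare_treatment_ops <- function(summaries, ref, alt,
                                  price_per_mwh = NULL) {
  row_of <- function(tr) {
    r <- summaries[summaries$treatment == tr, ]
    if (nrow(r) != 1) {
      abort(sprintf("Treatment '%s' not found in summaries.", tr),
            class = "curtailr_data_error")
    }
    r
  }
  r1 <- row_of(ref); r2 <- row_of(alt)
  if (r1$energy_mwh_per_turbine == 0) {
    abort("Reference energy is zero; percent loss undefined.",
          class = "curtailr_estimation_error")
  }
  if (is.null(price_per_mwh)) {
    price_per_mwh <- r1$revenue_per_turbine / r1$energy_mwh_per_turbine
  }
  ediff <- r1$energy_mwh_per_turbine - r2$energy_mwh_per_turbine
  tibble::tibble(
    comparison = paste(ref, "vs.", alt),
    energy_difference_mwh = ediff,
    revenue_difference = ediff * price_per_mwh,
    percent_loss = 100 * ediff / r1$energy_mwh_per_turbine
  )
}

#' All pairwise operation comparisons against a reference
#'
#' @inheritParams compare_treatment_ops
#' @param control The reference treatment; comparisons are
#'   control-vs-other plus all other ordered pairs.
#' @return A tibble of [compare_treatment_ops()] rows.
#' @export
compare_ops <- function(summaries, control = "control",
                        price_per_mwh = NULL) {
  trs <- summaries$treatment
  others <- setdiff(trs, control)
  pairs <- rbind(
    data.frame(ref = control, alt = others),
    if (length(others) >= 2) {
      pg <- t(utils::combn(others, 2))
      data.frame(ref = pg[, 1], alt = pg[, 2])
    }
  )
  purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    compare_treatment_ops(summaries, pairs$ref[i], pairs$alt[i],
                          price_per_mwh = price_per_mwh)
  })
}

#' Ratio of revenue losses between two comparisons
#'
#' How many times greater one treatment's revenue loss is than
#' another's, e.g. acoustic-informed curtailment versus wind-speed-only
#' curtailment, both relative to control.
#'
#' @param comp_a,comp_b One-row [compare_treatment_ops()] tibbles (or
#'   anything with a `revenue_difference` field).
#' @return `comp_a$revenue_difference / comp_b$revenue_difference`.
#' @examples
#' loss_ratio(list(revenue_difference = 3597.84),
#'            list(revenue_difference = 1291.76))
#' @export
loss_ratio <- function(comp_a, comp_b) {
  if (comp_b$revenue_difference == 0) {
    abort("Denominator revenue difference is zero.",
          class = "curtailr_estimation_error")
  }
  comp_a$revenue_difference / comp_b$revenue_difference
}
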