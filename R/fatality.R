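#' Horvitz-Thompson adjusted fatality estimate
#'
#' Adjusts the observed carcass count for imperfect detection: the
#' estimated number of fatalities per turbine over the study period is
#' \deqn{\hat M = \frac{C}{n_{\mathrm{turbines}} \times g_{\mathrm{search}}
#'   \times AC},}
#' where `C` is the count of carcasses found on scheduled searches inside
#' plots, `g_search` the detection probability within the searched area
#' ([detection_probability()]), and `AC` the area correction
#' ([area_correction()]).  The per-MW rate divides by turbine capacity.
#'
#' @param observed_count Total carcasses observed for the treatment.
#' @param g_search Detection probability given the carcass is in the
#'   searched area.
#' @param ac Area correction (fraction of carcasses expected in the
#'   searched area).
#' @param n_turbines Number of turbines in the treatment group.
#' @param capacity_mw Turbine nameplate capacity in MW (default 1.65).
#' @param treatment Optional label.
#' @return A one-row tibble: `treatment`, `observed_count`,
#'   `observed_per_turbine`, `g_search`, `ac`, `g_total`,
#'   `m_per_turbine`, `m_per_mw`.
#' @examples
#' estimate_fatalities(187, g_search = 0.83, ac = 0.92, n_turbines = 10)
#' @export
estimate_fatalities <- function(observed_count, g_search, ac, n_turbines,
                                capacity_mw = 1.65, treatment = NA_character_) {
  if (g_search * ac <= 0) {
    abort("g_search * AC must be positive; counts cannot be adjusted.",
          class = "curtailr_estimation_error")
  }
  m <- observed_count / (n_turbines * g_search * ac)
  tibble::tibble(
    treatment = treatment,
    observed_count = observed_count,
    observed_per_turbine = observed_count / n_turbines,
    g_search = g_search,
    ac = ac,
    g_total = g_search * ac,
    m_per_turbine = m,
    m_per_mw = m / capacity_mw
  )
}

#' Fatality reduction of a treatment relative to control
#'
#' `1 - m_treatment / m_control`: the proportional drop in estimated
#' fatalities.  Negative values indicate *increased* mortality under the
#' treatment.
#'
#' @param m_control,m_treatment Adjusted fatality rates (any common
#'   unit).
#' @return Proportion `<= 1`.
#' @examples
#' fatality_reduction(26.28, 14.12)  # 0.463
#' @export
fatality_reduction <- function(m_control, m_treatment) {
  if (any(m_control <= 0)) {
    abort("`m_control` must be positive.", class = "curtailr_estimation_error")
  }
  1 - m_treatment / m_control
}

#' Ratio of absolute fatality reductions between two treatments
#'
#' `(m_control - m_t1) / (m_control - m_t2)`: how many times more
#' fatalities treatment 1 removed than treatment 2, both relative to
#' control.  The ratio of *absolute* reductions is used (not the ratio
#' of percent reductions, which differs only through the shared control
#' denominator).
#'
#' @param m_control,m_t1,m_t2 Adjusted fatality rates.
#' @return A ratio.
#' @examples
#' reduction_ratio(26.28, 6.62, 14.12)
#' @export
reduction_ratio <- function(m_control, m_t1, m_t2) {
  if (any(m_control == m_t2)) {
    abort("Reduction ratio undefined: control equals the reference treatment.",
          class = "curtailr_estimation_error")
  }
  (m_control - m_t1) / (m_control - m_t2)
}

#' Are two estimates distinct by the CI-overlap rule?
#'
#' Two estimates are considered different when their confidence
#' intervals do not overlap.  Intervals are treated as closed: touching
#' endpoints overlap, hence *not* distinct.
#'
#' @param ci_a,ci_b Length-2 numeric vectors `c(lower, upper)`.
#' @return `TRUE` if the intervals are disjoint.
#' @examples
#' ci_overlap_distinct(c(1, 2), c(3, 4))  # TRUE
#' ci_overlap_distinct(c(1, 2), c(2, 3))  # FALSE (touching)
#' @export
ci_overlap_distinct <- function(ci_a, ci_b) {
  if (length(ci_a) != 2 || length(ci_b) != 2 ||
      ci_a[1] > ci_a[2] || ci_b[1] > ci_b[2]) {
    abort("`ci_a` and `ci_b` must be ordered length-2 intervals.")
  }
  max(ci_a[1], ci_b[1]) > min(ci_a[2], ci_b[2])
}
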