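#' Example study summary tables
#'
#' Small summary tables from a three-treatment curtailment field study
#' (10 control, 10 wind-speed-only curtailed, and 10 acoustic-informed
#' curtailed turbines searched daily over a 78-night season on 80 m
#' square plots), as printed in its published report.  Used in examples
#' and validation.
#'
#' * `"species_counts"`: observed bat fatalities included in analysis,
#'   by species and treatment, with a flag for migratory tree bats.
#' * `"distance_fits"`: fitted carcass distance-distribution parameters
#'   (Gompertz shape/scale per treatment and for the pooled
#'   TIMR + WOC sample) and the reported area corrections with 90% CIs
#'   (the TIMR-only fit was reported unreliable, with a near-zero scale).
#' * `"power_production"`: per-treatment mean in-window wind speed,
#'   study-period energy per turbine (MWh), and revenue per turbine at
#'   $40/MWh.  Printed revenues carry more significant digits than the
#'   printed energies (which are rounded to 0.1 MWh), so exact
#'   reproduction of revenue differences uses `revenue / price`.
#'
#' @param name One of `"species_counts"`, `"distance_fits"`,
#'   `"power_production"`.
#' @return A tibble.
#' @examples
#' curtail_example("species_counts")
#' @export
curtail_example <- function(name = c("species_counts", "distance_fits",
                                     "power_production")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "curtailr",
                      mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
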