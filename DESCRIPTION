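Package: curtailr
Title: Detection-Adjusted Bat Fatality Estimation and Curtailment
    Cost-Benefit Analysis for Wind Energy Facilities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates bat fatality rates at wind turbines from carcass
    search data, adjusting counts for searcher efficiency, carcass
    persistence, search schedule, and the fraction of carcasses expected
    to fall beyond square search plots.  Carcass distance distributions
    are fitted by truncated weighted likelihood with AICc model
    selection, and the resulting area correction, detection probability,
    and Horvitz-Thompson fatality estimates carry bootstrap confidence
    intervals.  Companion tools summarise turbine curtailment time,
    energy production, and revenue to compare the cost of wind-speed-only
    and acoustic-informed curtailment strategies, and a synthetic study
    generator provides complete simulated data sets with known ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    flexsurv,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    MASS,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
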