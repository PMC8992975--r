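small_cfg <- function(seed = 1, n_nights = 30, ...) {
  sim_config(seed = seed, n_nights = n_nights, ...)
}

test_that("simulation is deterministic given the seed", {
  s1 <- simulate_study(small_cfg(seed = 3))
  s2 <- simulate_study(small_cfg(seed = 3))
  expect_identical(s1$carcasses, s2$carcasses)
  expect_identical(s1$seef_trials, s2$seef_trials)
  expect_identical(s1$persistence_trials, s2$persistence_trials)
  s3 <- simulate_study(small_cfg(seed = 4))
  expect_false(identical(s1$carcasses, s3$carcasses))
})

test_that("zero fatality rate produces empty carcass tables", {
  cfg <- small_cfg(treatments = tibble::tibble(
    treatment = "control", rate = 0, dist_family = "gompertz",
    dist_shape = 0.0728, dist_scale = 0.0094
  ))
  sim <- simulate_study(cfg)
  expect_equal(nrow(sim$fatalities), 0)
  expect_equal(nrow(sim$carcasses), 0)
})

test_that("observed counts track the analytic expectation M * n * g_total", {
  # large true M so 3*sqrt(expected) is a tight relative band
  cfg <- sim_config(
    seed = 5, n_nights = 78,
    treatments = tibble::tibble(
      treatment = "control", rate = 50, dist_family = "gompertz",
      dist_shape = 0.0728, dist_scale = 0.0094
    )
  )
  sim <- simulate_study(cfg)
  expected <- sim$truth$expected_observed
  observed <- nrow(sim$carcasses)
  expect_lt(abs(observed - expected), 3 * sqrt(expected))
  # observed carcasses are a subset of true fatalities, inside the plot
  expect_true(all(sim$carcasses$carcass_id %in% sim$fatalities$carcass_id))
  expect_true(all(sim$carcasses$distance_m <
                    corner_truncation_distance(square_plot(cfg$half_width))))
})

test_that("trial tables respect their protocols", {
  sim <- simulate_study(small_cfg(seed = 6))
  expect_equal(nrow(sim$seef_trials), 42)
  expect_true(all(!sim$seef_trials$found | sim$seef_trials$available))
  pt <- sim$persistence_trials
  expect_equal(nrow(pt), 56)
  expect_true(all(pt$censored | pt$last_present_d < pt$first_absent_d))
  expect_true(all(pt$last_present_d[pt$censored] == 30))
  checks <- c(0, 1, 2, 3, 4, 7, 10, 14, 20, 30)
  expect_true(all(pt$last_present_d %in% checks))
})

test_that("curtailment rules are enforced in simulated operations", {
  cfg <- small_cfg(seed = 7, n_nights = 10)
  ops <- simulate_ops(cfg)
  woc <- ops[ops$treatment == "WOC", ]
  expect_true(all(woc$curtailed ==
                    (woc$in_treatment_window & woc$wind_speed_mps < 4.5)))
  timr <- ops[ops$treatment == "TIMR", ]
  expect_true(all(timr$wind_speed_mps[timr$curtailed] < 8.0))
  expect_true(all(timr$in_treatment_window[timr$curtailed]))
  ctrl <- ops[ops$treatment == "control", ]
  expect_true(!any(ctrl$curtailed))
  # curtailed bins produce no energy
  expect_true(all(ops$energy_mwh[ops$curtailed] == 0))
})

test_that("the power curve is monotone between cut-in and rated speed", {
  cfg <- sim_config()
  v <- seq(0, 20, by = 0.1)
  p <- power_curve(v, cfg)
  expect_true(all(diff(p) >= 0))
  expect_equal(p[v < 3.5], rep(0, sum(v < 3.5)))
  expect_equal(max(p), cfg$capacity_mw)
  expect_equal(power_curve(13.5, cfg), cfg$capacity_mw)
  expect_equal(power_curve(18, cfg), cfg$capacity_mw)
})

test_that("simulated wind matches the configured mean", {
  cfg <- small_cfg(seed = 8, n_nights = 20)
  ops <- simulate_ops(cfg)
  expect_equal(mean(ops$wind_speed_mps), 5.7, tolerance = 0.1)
})
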