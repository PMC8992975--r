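test_that("searcher efficiency is the proportion found among available", {
  est <- estimate_seef(make_seef_trials(30, 50), ci_level = 0.90)
  expect_equal(est$p, 0.6)
  # Wilson score interval, cross-checked against its closed form
  expect_equal(est$ci_lower, 0.4837, tolerance = 1e-3)
  expect_equal(est$ci_upper, 0.7059, tolerance = 1e-3)
  expect_true(est$ci_lower <= est$p && est$p <= est$ci_upper)

  # unavailable carcasses are excluded from the denominator
  est2 <- estimate_seef(make_seef_trials(30, 50, n_unavailable = 10))
  expect_equal(est2$p, 0.6)
  expect_equal(est2$n_available, 50)

  # boundary: nothing found
  est0 <- estimate_seef(make_seef_trials(0, 10))
  expect_equal(est0$p, 0)
  expect_equal(est0$ci_lower, 0)
  expect_error(estimate_seef(make_seef_trials(0, 0, 5)),
               class = "curtailr_estimation_error")
})

test_that("Wilson intervals always lie in [0,1] and contain p", {
  for (x in c(0, 1, 5, 25, 42)) {
    for (n in c(42, 56)) {
      if (x > n) next
      est <- estimate_seef(make_seef_trials(x, n))
      expect_gte(est$ci_lower, 0)
      expect_lte(est$ci_upper, 1)
      expect_true(est$ci_lower <= est$p && est$p <= est$ci_upper)
    }
  }
})

test_that("detection decays geometrically across searches", {
  expect_equal(seef_at_search(0.6, 0.7, 1), 0.6)
  expect_equal(seef_at_search(0.6, 0.7, 3), 0.294)
  expect_equal(seef_at_search(0.6, 1, 7), 0.6)
  expect_error(seef_at_search(0.6, 0.7, 0), "integer")
})

test_that("interval-censored persistence fit matches the closed-form oracle", {
  # one removal in (0,1], one censored at 30: stationarity gives
  # exp(-theta) = 30 (1 - exp(-theta)), theta = log(31/30)
  tr <- tibble::tibble(last_present_d = c(0, 30), first_absent_d = c(1, NA),
                       censored = c(FALSE, TRUE))
  fit <- fit_persistence(tr, "exponential")
  expect_equal(fit$params[["rate"]], log(31 / 30), tolerance = 1e-4)
  expect_equal(fit$median_days, log(2) / log(31 / 30), tolerance = 1e-3)

  # the same maximum found by direct grid search of the likelihood
  th <- seq(0.001, 0.2, by = 1e-4)
  ll <- log(1 - exp(-th)) - 30 * th
  expect_equal(fit$params[["rate"]], th[which.max(ll)], tolerance = 1e-3)
})

test_that("lognormal persistence recovers the generating median", {
  set.seed(81)
  times <- rlnorm(400, log(8.7), 1.4)
  trials <- censor_through_checks(times)
  fit <- fit_persistence(trials, "lognormal")
  expect_equal(fit$median_days, 8.7, tolerance = 0.15)
  expect_equal(unname(fit$params["meanlog"]), log(8.7), tolerance = 0.1)
  # a right-censored record is the same as an interval (30, Inf)
  expect_error(fit_persistence(
    tibble::tibble(last_present_d = 30, first_absent_d = NA,
                   censored = TRUE)),
    class = "curtailr_estimation_error")
})

test_that("AICc prefers the parsimonious persistence family", {
  mk <- function(aicc, family) {
    structure(list(aicc = aicc, family = family, reliable = TRUE,
                   n_params = 2L, params = c(a = 1), median_days = 5),
              class = "persistence_fit")
  }
  fits <- list(mk(210.1, "weibull"), mk(208.0, "lognormal"),
               mk(215.3, "loglogistic"), mk(209.9, "exponential"))
  expect_equal(select_persistence_model(fits)$aicc, 208.0)
  expect_equal(select_persistence_model(fits[2])$family, "lognormal")

  # exponential data: AICc should prefer exponential over weibull in
  # most simulations (the extra parameter buys nothing)
  set.seed(82)
  wins <- 0
  for (i in 1:40) {
    trials <- censor_through_checks(stats::rexp(56, 1 / 8))
    fits <- fit_persistence_models(trials,
                                   families = c("exponential", "weibull"))
    if (select_persistence_model(fits)$family == "exponential") {
      wins <- wins + 1
    }
  }
  expect_gte(wins / 40, 0.6)
})

test_that("interval availability matches closed forms and is monotone", {
  f_exp <- fake_persistence("exponential", c(rate = 0.1))
  expect_equal(interval_availability(f_exp, 1), (1 - exp(-0.1)) / 0.1,
               tolerance = 1e-8)
  # near-zero interval -> 1; longer intervals are harder to persist
  expect_equal(interval_availability(f_exp, 1e-6), 1, tolerance = 1e-4)
  r <- vapply(c(0.5, 1, 2, 5, 10), function(I) {
    interval_availability(f_exp, I)
  }, numeric(1))
  expect_true(all(diff(r) < 0))
  expect_true(all(r > 0 & r <= 1))
})

test_that("detection probability matches the term-by-term oracle", {
  # two searches at t = 1, 2, arrival at t = 0 exactly, S(t) = e^{-0.2 t}:
  # 0.40937 + 0.13406
  g <- detection_probability(list(p = 0.5, k = 0.8),
                             function(t) exp(-0.2 * t),
                             search_offsets = c(1, 2), arrival = "point")
  expect_equal(g, 0.54343, tolerance = 1e-5)

  # perfect searcher, immortal carcass
  expect_equal(detection_probability(list(p = 1, k = 1),
                                     function(t) rep(1, length(t))), 1)
  # one chance only when k = 0 and no removal
  expect_equal(detection_probability(list(p = 0.6, k = 0),
                                     function(t) rep(1, length(t))), 0.6)
})

test_that("detection probability increases in p, k, and persistence", {
  S_fast <- function(t) exp(-0.3 * t)
  S_slow <- function(t) exp(-0.1 * t)
  g <- function(p, k, S) detection_probability(list(p = p, k = k), S)
  expect_true(g(0.4, 0.7, S_fast) < g(0.6, 0.7, S_fast))
  expect_true(g(0.6, 0.5, S_fast) < g(0.6, 0.9, S_fast))
  expect_true(g(0.6, 0.7, S_fast) < g(0.6, 0.7, S_slow))
})

test_that("schedule gaps lower the detection probability", {
  S <- function(t) exp(-0.2 * t)
  g_daily <- detection_probability(list(p = 0.5, k = 0.8), S,
                                   search_offsets = 1:20)
  g_gap <- detection_probability(list(p = 0.5, k = 0.8), S,
                                 search_offsets = c(1, 3:20))
  expect_lt(g_gap, g_daily)
})
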