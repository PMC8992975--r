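test_that("TWL with psi = 1 and infinite truncation equals plain MLE", {
  # On a plot so large that every observation is fully inside, weights
  # collapse to 1 and F(tau) to 1, so the fit is the ordinary MLE.
  huge <- square_plot(1e5)
  set.seed(31)
  d <- dist_quantile(runif(400), "rayleigh", NA, 22)

  fit <- twl_fit(d, "rayleigh", huge)
  # closed-form Rayleigh MLE: sigma^2 = mean(d^2) / 2
  expect_equal(fit$scale, sqrt(mean(d^2) / 2), tolerance = 1e-4)

  # gamma vs an independent optimiser (MASS::fitdistr)
  set.seed(32)
  dg <- dist_quantile(runif(400), "gamma", 2.5, 10)
  fitg <- twl_fit(dg, "gamma", huge)
  ref <- MASS::fitdistr(dg, "gamma")
  expect_equal(fitg$shape, unname(ref$estimate["shape"]), tolerance = 1e-2)
  expect_equal(1 / fitg$scale, unname(ref$estimate["rate"]), tolerance = 1e-2)
})

test_that("TWL recovers known Gompertz parameters from plot-thinned data", {
  plot <- square_plot(40)
  d <- sample_plot_distances(500, "gompertz", 0.0589, 0.0066, plot, seed = 41)
  fit <- twl_fit(d, "gompertz", plot)
  expect_true(fit$reliable)
  expect_lt(abs(fit$shape - 0.0589) / 0.0589, 0.25)
  expect_lt(abs(fit$scale - 0.0066) / 0.0066, 0.50)
  # fitted mode within 15% of the true 37.2 m
  expect_lt(abs(fit$mode_m - 37.16) / 37.16, 0.15)
})

test_that("samples with mass piling up at the truncation bound are flagged", {
  plot <- square_plot(40)
  # density increasing right up to the corner distance: the truncated
  # sample cannot contain the mode
  set.seed(51)
  d <- 56.5 * runif(60)^0.25
  d <- d[d < plot$truncation_distance]
  fits <- suppressWarnings(fit_carcass_distances(d, plot))
  expect_true(length(fits) >= 3)
  expect_true(all(!purrr::map_lgl(fits, "reliable")))
  expect_error(select_distance_model(fits),
               class = "curtailr_selection_error")
})

test_that("fit errors are informative", {
  plot <- square_plot(40)
  expect_error(twl_fit(c(5, 10, 60), "gamma", plot), "truncation",
               class = "curtailr_data_error")
  expect_error(twl_fit(c(5, 10), "gamma", plot),
               class = "curtailr_insufficient_data")
  expect_error(twl_fit(numeric(0), "gamma", plot),
               class = "curtailr_data_error")
})

test_that("AICc selection takes the minimum with documented tie-breaks", {
  mk <- function(aicc, family, reliable = TRUE) {
    structure(list(aicc = aicc, family = family, reliable = reliable,
                   shape = 1, scale = 1),
              class = "twl_fit")
  }
  fits <- list(mk(100.0, "gamma"), mk(98.5, "weibull"), mk(103.2, "gompertz"))
  expect_equal(select_distance_model(fits)$aicc, 98.5)
  expect_equal(select_distance_model(fits[1])$family, "gamma")
  # equal AICc, equal parameter count: alphabetical family
  tie <- list(mk(100, "weibull"), mk(100, "gamma"))
  expect_equal(select_distance_model(tie)$family, "gamma")
  # unreliable fits are never selected
  mix <- list(mk(90, "gamma", reliable = FALSE), mk(95, "weibull"))
  expect_equal(select_distance_model(mix)$family, "weibull")
})

test_that("pooling concatenates samples and keeps provenance", {
  woc <- tibble::tibble(distance_m = runif(78, 0, 40), treatment = "WOC")
  timr <- tibble::tibble(distance_m = runif(31, 0, 40), treatment = "TIMR")
  pooled <- pool_distance_samples(woc, timr, label = "TIMR + WOC")
  expect_equal(nrow(pooled), 109)
  expect_setequal(unique(pooled$source), c("WOC", "TIMR"))
  expect_equal(unique(pooled$treatment), "TIMR + WOC")
  # self-pooling doubles n; empty second sample copies the first
  expect_equal(nrow(pool_distance_samples(woc, woc)), 156)
  expect_equal(nrow(pool_distance_samples(woc, numeric(0))), 78)
})
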