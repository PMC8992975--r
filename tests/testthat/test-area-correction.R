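fake_fit <- function(family, shape, scale, reliable = TRUE) {
  list(family = family, shape = shape, scale = scale, reliable = reliable)
}

test_that("area correction has the right limits", {
  plot <- square_plot(40)
  # all mass well inside the fully-searched radius
  expect_gt(area_correction(fake_fit("rayleigh", NA, 10), plot), 0.999)
  # essentially all mass beyond the corner distance
  expect_lt(area_correction(fake_fit("truncated_normal", 150, 5), plot),
            1e-6)
})

test_that("area correction matches a 2-D Monte-Carlo oracle", {
  plot <- square_plot(40)
  set.seed(61)
  cases <- list(
    c(0.0728, 0.0094),  # control-like, mode 28 m
    c(0.0589, 0.0066),  # WOC-like, mode 37 m
    c(0.0441, 0.0055)   # pooled-like, mode 47 m
  )
  for (pr in cases) {
    ac <- area_correction(fake_fit("gompertz", pr[1], pr[2]), plot)
    d <- dist_quantile(runif(2e5), "gompertz", pr[1], pr[2])
    th <- runif(2e5, 0, 2 * pi)
    frac <- mean(abs(d * cos(th)) <= 40 & abs(d * sin(th)) <= 40)
    se <- sqrt(frac * (1 - frac) / 2e5)
    expect_lt(abs(ac - frac), 3 * se)
  }
})

test_that("AC is bracketed by F(a) and F(tau) and monotone in location", {
  plot <- square_plot(40)
  a <- plot$half_width; tau <- plot$truncation_distance
  for (pr in list(fake_fit("gompertz", 0.0589, 0.0066),
                  fake_fit("weibull", 2, 30),
                  fake_fit("truncated_normal", 35, 12))) {
    ac <- area_correction(pr, plot)
    expect_gte(ac, dist_cdf(a, pr$family, pr$shape, pr$scale) - 1e-9)
    expect_lte(ac, dist_cdf(tau, pr$family, pr$shape, pr$scale) + 1e-9)
  }
  # shifting a truncated normal outward strictly decreases AC
  acs <- vapply(seq(10, 60, by = 10), function(mu) {
    area_correction(fake_fit("truncated_normal", mu, 12), plot)
  }, numeric(1))
  expect_true(all(diff(acs) < 0))
})

test_that("unreliable fits are refused without force", {
  plot <- square_plot(40)
  bad <- fake_fit("gompertz", 0.1, 1e-8, reliable = FALSE)
  expect_error(area_correction(bad, plot),
               class = "curtailr_unreliable_fit")
  expect_silent(area_correction(bad, plot, force = TRUE))
})

test_that("bootstrap AC gives ordered, reproducible percentile intervals", {
  plot <- square_plot(40)
  d <- sample_plot_distances(150, "gompertz", 0.0728, 0.0094, plot,
                             seed = 71)
  bt <- bootstrap_area_correction(d, "gompertz", plot, n_boot = 200,
                                  seed = 5)
  expect_lte(bt$ci_lower, bt$estimate)
  expect_gte(bt$ci_upper, bt$estimate)
  expect_equal(bt$n_bootstrap + bt$n_failed, 200)
  bt2 <- bootstrap_area_correction(d, "gompertz", plot, n_boot = 200,
                                   seed = 5)
  expect_identical(bt[c("estimate", "ci_lower", "ci_upper")],
                   bt2[c("estimate", "ci_lower", "ci_upper")])

  # degenerate sample: all resamples identical, zero-width interval
  dd <- rep(17.3, 30)
  btd <- bootstrap_area_correction(dd, "rayleigh", plot, n_boot = 50,
                                   seed = 2)
  expect_equal(btd$ci_lower, btd$ci_upper, tolerance = 1e-6)
})
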