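params_grid <- list(
  list(family = "gamma", shape = 2.5, scale = 10),
  list(family = "gompertz", shape = 0.0728, scale = 0.0094),
  list(family = "rayleigh", shape = NA, scale = 20),
  list(family = "truncated_normal", shape = 30, scale = 15),
  list(family = "truncated_normal", shape = -5, scale = 20),
  list(family = "weibull", shape = 1.8, scale = 30)
)

test_that("every family CDF starts at 0, is non-decreasing and reaches 1", {
  x <- seq(0, 500, by = 0.5)
  for (pr in params_grid) {
    Fx <- dist_cdf(x, pr$family, pr$shape, pr$scale)
    expect_equal(Fx[1], 0, info = pr$family)
    expect_true(all(diff(Fx) >= -1e-12), info = pr$family)
    expect_equal(Fx[length(Fx)], 1, tolerance = 1e-6, info = pr$family)
  }
})

test_that("CDF agrees with numerical integration of the density", {
  for (pr in params_grid) {
    for (x in c(15, 40)) {
      num <- integrate(function(u) dist_density(u, pr$family, pr$shape,
                                                pr$scale),
                       0, x, rel.tol = 1e-10)$value
      expect_equal(dist_cdf(x, pr$family, pr$shape, pr$scale), num,
                   tolerance = 1e-6, info = pr$family)
    }
  }
})

test_that("gompertz hazard parametrization behaves as specified", {
  # closed form at the control-treatment parameter set
  expect_equal(dist_cdf(40, "gompertz", 0.0728, 0.0094), 0.894,
               tolerance = 1e-3)
  # small-shape limit approaches the exponential CDF
  lam <- 0.05
  expect_equal(dist_cdf(10, "gompertz", 1e-8, lam), 1 - exp(-lam * 10),
               tolerance = 1e-6)
  # mode formula against numeric argmax of the density
  xg <- seq(0, 200, by = 0.01)
  dens <- dist_density(xg, "gompertz", 0.0728, 0.0094)
  expect_equal(dist_mode("gompertz", 0.0728, 0.0094), xg[which.max(dens)],
               tolerance = 1e-2)
  expect_equal(dist_mode("gompertz", 0.0728, 0.0094), 28.118,
               tolerance = 1e-3)
})

test_that("quantile inverts the CDF", {
  for (pr in params_grid) {
    for (q in c(0.1, 0.5, 0.9)) {
      x <- dist_quantile(q, pr$family, pr$shape, pr$scale)
      expect_equal(dist_cdf(x, pr$family, pr$shape, pr$scale), q,
                   tolerance = 1e-6, info = pr$family)
    }
  }
})

test_that("invalid parameters are rejected", {
  expect_error(dist_cdf(1, "gamma", -1, 2), class = "curtailr_parameter_error")
  expect_error(dist_cdf(1, "rayleigh", NA, -3),
               class = "curtailr_parameter_error")
  expect_error(dist_cdf(1, "cauchy", 1, 1), "must be one of")
})
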