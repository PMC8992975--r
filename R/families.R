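#' Carcass distance-density families
#'
#' Five candidate families for the distribution of carcass fall distance
#' from the turbine base, each parametrised by a `shape` and `scale` slot
#' so fitted parameters print uniformly:
#'
#' * `gamma`: standard shape/scale gamma.
#' * `gompertz`: hazard `h(x) = scale * exp(shape * x)`, so
#'   `F(x) = 1 - exp(-(scale/shape) * (exp(shape * x) - 1))`; `shape` is
#'   the exponential hazard growth rate `b` and `scale` the baseline
#'   hazard `lambda`.  The density mode is `log(shape/scale)/shape` when
#'   `shape > scale`, otherwise 0.
#' * `rayleigh`: single parameter `sigma` stored in `scale`
#'   (`shape` is `NA`); `F(x) = 1 - exp(-x^2 / (2 sigma^2))`.
#' * `truncated_normal`: normal with mean `shape` and sd `scale`,
#'   truncated to `[0, Inf)`.
#' * `weibull`: standard shape/scale Weibull.
#'
#' @param family One of `r paste0('"', distance_families(), '"', collapse = ", ")`.
#' @param shape,scale Family parameters as above.
#' @param x Distance(s) in metres, `>= 0`.
#' @param p Probabilities in `[0, 1]`.
#'
#' @return `distance_families()` returns the vector of family names;
#'   `dist_density()`, `dist_cdf()` and `dist_quantile()` return numeric
#'   vectors; `dist_mode()` the density mode in metres;
#'   `dist_n_params()` the number of free parameters.
#'
#' @examples
#' dist_cdf(40, "gompertz", shape = 0.0728, scale = 0.0094)
#' dist_mode("gompertz", shape = 0.0728, scale = 0.0094)
#' @name distance-families
NULL

#' @rdname distance-families
#' @export
distance_families <- function() {
  c("gamma", "gompertz", "rayleigh", "truncated_normal", "weibull")
}

check_family <- function(family) {
  if (!is.character(family) || length(family) != 1 ||
      !family %in% distance_families()) {
    abort(paste0(
      "`family` must be one of: ",
      paste(distance_families(), collapse = ", ")
    ))
  }
  family
}

check_params <- function(family, shape, scale) {
  ok <- switch(family,
    gamma = is.finite(shape) && is.finite(scale) && shape > 0 && scale > 0,
    gompertz = is.finite(shape) && is.finite(scale) && shape > 0 && scale > 0,
    rayleigh = is.finite(scale) && scale > 0,
    truncated_normal = is.finite(shape) && is.finite(scale) && scale > 0,
    weibull = is.finite(shape) && is.finite(scale) && shape > 0 && scale > 0
  )
  if (!ok) {
    abort(sprintf("Invalid parameters for family '%s'.", family),
          class = "curtailr_parameter_error")
  }
  invisible(TRUE)
}

#' @rdname distance-families
#' @export
dist_n_params <- function(family) {
  check_family(family)
  if (family == "rayleigh") 1L else 2L
}

#' @rdname distance-families
#' @export
dist_density <- function(x, family, shape, scale) {
  check_family(family)
  check_params(family, shape, scale)
  if (any(x < 0)) abort("`x` must be >= 0.")
  switch(family,
    gamma = dgamma(x, shape = shape, scale = scale),
    gompertz = flexsurv::dgompertz(x, shape = shape, rate = scale),
    rayleigh = x / scale^2 * exp(-x^2 / (2 * scale^2)),
    truncated_normal = dnorm(x, shape, scale) /
      pnorm(shape / scale),
    weibull = dweibull(x, shape = shape, scale = scale)
  )
}

#' @rdname distance-families
#' @export
dist_cdf <- function(x, family, shape, scale) {
  check_family(family)
  check_params(family, shape, scale)
  if (any(x < 0)) abort("`x` must be >= 0.")
  switch(family,
    gamma = pgamma(x, shape = shape, scale = scale),
    gompertz = flexsurv::pgompertz(x, shape = shape, rate = scale),
    rayleigh = 1 - exp(-x^2 / (2 * scale^2)),
    truncated_normal = (pnorm((x - shape) / scale) - pnorm(-shape / scale)) /
      pnorm(shape / scale),
    weibull = pweibull(x, shape = shape, scale = scale)
  )
}

#' @rdname distance-families
#' @export
dist_quantile <- function(p, family, shape, scale) {
  check_family(family)
  check_params(family, shape, scale)
  if (any(p < 0 | p > 1)) abort("`p` must be in [0, 1].")
  switch(family,
    gamma = qgamma(p, shape = shape, scale = scale),
    gompertz = flexsurv::qgompertz(p, shape = shape, rate = scale),
    rayleigh = scale * sqrt(-2 * log1p(-p)),
    truncated_normal = shape + scale *
      qnorm(pnorm(-shape / scale) + p * pnorm(shape / scale)),
    weibull = qweibull(p, shape = shape, scale = scale)
  )
}

#' @rdname distance-families
#' @export
dist_mode <- function(family, shape, scale) {
  check_family(family)
  check_params(family, shape, scale)
  switch(family,
    gamma = if (shape > 1) (shape - 1) * scale else 0,
    gompertz = if (shape > scale) log(shape / scale) / shape else 0,
    rayleigh = scale,
    truncated_normal = max(0, shape),
    weibull = if (shape > 1) scale * ((shape - 1) / shape)^(1 / shape) else 0
  )
}

# Parameter transform to an unconstrained optimisation scale and back.
# truncated_normal mean is unconstrained; all other parameters positive.
par_to_opt <- function(family, shape, scale) {
  if (family == "rayleigh") return(log(scale))
  if (family == "truncated_normal") return(c(shape, log(scale)))
  c(log(shape), log(scale))
}

opt_to_par <- function(family, theta) {
  if (family == "rayleigh") return(list(shape = NA_real_, scale = exp(theta[1])))
  if (family == "truncated_normal") {
    return(list(shape = theta[1], scale = exp(theta[2])))
  }
  list(shape = exp(theta[1]), scale = exp(theta[2]))
}

# Deterministic starting values for the optimiser, spread around
# moment-style guesses from the observed (truncated) sample.
family_starts <- function(family, d) {
  m <- mean(d)
  s <- max(stats::sd(d), 1e-3)
  starts <- switch(family,
    gamma = list(
      c(m^2 / s^2, s^2 / m), c(1, m), c(2, m / 2), c(4, m / 4), c(0.5, 2 * m)
    ),
    gompertz = list(
      c(0.05, 0.01), c(0.02, 0.02), c(0.1, 0.005), c(0.05, 0.002),
      c(1 / m, 0.5 / m)
    ),
    rayleigh = list(
      sqrt(mean(d^2) / 2), m, s, m / 2, 2 * m
    ),
    truncated_normal = list(
      c(m, s), c(m, 2 * s), c(m / 2, s), c(0, m), c(2 * m, s)
    ),
    weibull = list(
      c(1.5, m), c(1, m), c(2, m), c(3, m), c(0.8, m)
    )
  )
  lapply(starts, function(p) {
    if (family == "rayleigh")

      par_to_opt(family, NA_real_, p)
    else par_to_opt(family, p[1], p[2])
  })
}
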