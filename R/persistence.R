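#' Carcass persistence from interval-censored removal trials
#'
#' Trial carcasses are placed and checked on a schedule (daily for the
#' first days, then less often, with censoring at the end of monitoring);
#' removal is therefore observed only to an interval
#' `(last_present_d, first_absent_d]`.  The removal-time distribution is
#' fitted by maximum likelihood on these intervals — the contribution of
#' an uncensored carcass is `S(t_lo) - S(t_hi)` and of a censored carcass
#' `S(t_cens)` — via [survival::survreg()] with an intercept-only model
#' (no covariates).  Candidate families are exponential, Weibull,
#' lognormal and log-logistic, compared by AICc.
#'
#' @param data A data frame with columns `last_present_d` (days since
#'   placement the carcass was last seen), `first_absent_d` (days since
#'   placement it was first missing; ignored for censored records), and
#'   optionally a logical `censored` (still present at the final check,
#'   at `last_present_d` days).
#' @param family One of `"exponential"`, `"weibull"`, `"lognormal"`,
#'   `"loglogistic"`.
#' @return An object of class `persistence_fit`: `family`, `params`
#'   (named numeric vector), `loglik`, `aicc`, `n`, `n_params`,
#'   `median_days`, `reliable`.
#' @examples
#' trials <- tibble::tibble(
#'   last_present_d = c(0, 2, 4, 10),
#'   first_absent_d = c(1, 3, 7, NA),
#'   censored = c(FALSE, FALSE, FALSE, TRUE)
#' )
#' fit_persistence(trials, "exponential")
#' @export
fit_persistence <- function(data, family = c("exponential", "weibull",
                                             "lognormal", "loglogistic")) {
  family <- match.arg(family)
  req <- c("last_present_d", "first_absent_d")
  if (!all(req %in% names(data))) {
    abort("`data` must have `last_present_d` and `first_absent_d` columns.",
          class = "curtailr_data_error")
  }
  lo <- as.numeric(data$last_present_d)
  hi <- as.numeric(data$first_absent_d)
  cens <- if ("censored" %in% names(data)) as.logical(data$censored)
          else is.na(hi) | is.infinite(hi)
  if (any(!cens & (is.na(hi) | lo >= hi))) {
    abort("Uncensored records need last_present_d < first_absent_d.",
          class = "curtailr_data_error")
  }
  if (all(cens)) {
    abort("All records censored; persistence is not identifiable.",
          class = "curtailr_estimation_error")
  }
  n <- length(lo)

  # interval2 coding: (NA, t] left-censored, [t, NA) right-censored.
  t1 <- ifelse(cens, lo, ifelse(lo <= 0, NA, lo))
  t2 <- ifelse(cens, NA, hi)
  srv <- survival::Surv(time = t1, time2 = t2, type = "interval2")
  sr <- tryCatch(
    survival::survreg(srv ~ 1, dist = family,
                      control = survival::survreg.control(maxiter = 100)),
    error = function(e) {
      abort(sprintf("Persistence fit failed for family '%s': %s",
                    family, conditionMessage(e)),
            class = "curtailr_fit_error")
    }
  )

  mu <- unname(coef(sr)[1])
  sc <- sr$scale
  params <- switch(family,
    exponential = c(rate = exp(-mu)),
    weibull = c(shape = 1 / sc, scale = exp(mu)),
    lognormal = c(meanlog = mu, sdlog = sc),
    loglogistic = c(shape = 1 / sc, scale = exp(mu))
  )
  n_params <- if (family == "exponential") 1L else 2L
  ll <- as.numeric(logLik(sr))
  aicc <- -2 * ll + 2 * n_params + 2 * n_params * (n_params + 1) /
    (n - n_params - 1)
  median_days <- switch(family,
    exponential = log(2) / params[["rate"]],
    weibull = params[["scale"]] * log(2)^(1 / params[["shape"]]),
    lognormal = exp(params[["meanlog"]]),
    loglogistic = params[["scale"]]
  )
  structure(
    list(family = family, params = params, loglik = ll, aicc = aicc,
         n = n, n_params = n_params, median_days = median_days,
         reliable = is.finite(aicc) && median_days > 0),
    class = "persistence_fit"
  )
}

#' @export
print.persistence_fit <- function(x, ...) {
  cat(sprintf(
    "<persistence_fit> %s (%s): median %.2f d (n = %d, AICc = %.2f)\n",
    x$family,
    paste(names(x$params), signif(x$params, 4), sep = " = ", collapse = ", "),
    x$median_days, x$n, x$aicc
  ))
  invisible(x)
}

#' Fit all candidate persistence families
#'
#' @inheritParams fit_persistence
#' @param families Families to try.
#' @return A named list of `persistence_fit` objects.
#' @export
fit_persistence_models <- function(data, families = c("exponential",
                                                      "weibull", "lognormal",
                                                      "loglogistic")) {
  fits <- list()
  for (fam in families) {
    fit <- tryCatch(fit_persistence(data, fam), error = function(e) {
      warn(sprintf("Persistence family '%s' failed: %s", fam,
                   conditionMessage(e)))
      NULL
    })
    if (!is.null(fit)) fits[[fam]] <- fit
  }
  fits
}

#' @rdname select_by_aicc
#' @export
select_persistence_model <- function(fits) {
  fit <- select_by_aicc(fits)
  if (!inherits(fit, "persistence_fit")) {
    abort("`fits` must be `persistence_fit` objects.")
  }
  fit
}

#' Survival function of a fitted persistence distribution
#'
#' @param fit A [fit_persistence()] result.
#' @param t Time(s) in days.
#' @return `S(t)`, the probability a carcass persists beyond `t` days.
#' @export
persistence_survival <- function(fit, t) {
  if (any(t < 0)) abort("`t` must be >= 0.")
  p <- fit$params
  switch(fit$family,
    exponential = exp(-p[["rate"]] * t),
    weibull = exp(-(t / p[["scale"]])^p[["shape"]]),
    lognormal = 1 - plnorm(t, p[["meanlog"]], p[["sdlog"]]),
    loglogistic = 1 / (1 + (t / p[["scale"]])^p[["shape"]])
  )
}

#' Probability a carcass persists to the next search
#'
#' For a carcass arriving at a uniformly distributed time within a
#' search interval of length `I` days, the probability it is still
#' present at the end-of-interval search is
#' \deqn{r = \frac{1}{I} \int_0^I S(u)\,du,}
#' computed by adaptive quadrature.  `r` is non-increasing in the
#' interval length and tends to 1 as the interval shrinks.
#'
#' @param fit A [fit_persistence()] result.
#' @param interval_days Search interval length in days (> 0).
#' @return Probability in `(0, 1]`.
#' @examples
#' fit <- list(family = "exponential", params = c(rate = 0.1))
#' class(fit) <- "persistence_fit"
#' interval_availability(fit, 1)  # (1 - exp(-0.1)) / 0.1
#' @export
interval_availability <- function(fit, interval_days = 1) {
  if (!is.numeric(interval_days) || interval_days <= 0) {
    abort("`interval_days` must be > 0.")
  }
  integrate(function(u) persistence_survival(fit, u), 0, interval_days,
            rel.tol = 1e-9)$value / interval_days
}
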