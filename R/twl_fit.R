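#' Truncated weighted likelihood fit of a carcass distance distribution
#'
#' Fits a distance-density family to carcass distances observed on a
#' square search plot.  Observed distances are right-truncated at the
#' plot's corner distance `tau`, and each observation is up-weighted by
#' the inverse of its inclusion probability `psi(d)` (the fraction of the
#' radius-`d` circle inside the plot, [circle_inclusion_fraction()]) to
#' account for the reduced search effort beyond the plot half-width.
#' The fit maximises
#' \deqn{\sum_i w_i [\log f(d_i;\theta) - \log F(\tau;\theta)],\quad
#'       w_i \propto 1/\psi(d_i),\ \sum_i w_i = n,}
#' by bounded quasi-Newton iteration from several deterministic starting
#' points.  AICc is computed on the raw sample size with the family's
#' number of free parameters.
#'
#' A fit is flagged unreliable (`reliable = FALSE`) when the fitted
#' density mode lies at or beyond `0.95 * tau` — the truncated sample
#' then carries almost no information about the right tail, the hallmark
#' failure mode of truncated-likelihood distance fitting when the search
#' radius does not cover the mode of the fall distribution — or when the
#' fit is otherwise degenerate.
#'
#' @param data A data frame with a `distance_m` column (metres), or a
#'   numeric vector of distances.  All distances must be in
#'   `[0, tau)`.
#' @param family A distance family name; see [distance_families()].
#' @param plot A [square_plot()].
#' @param treatment Optional label recorded on the fit.
#' @param start Optional starting parameters `c(shape, scale)` tried in
#'   addition to the built-in deterministic starts.
#' @param multistart If `FALSE` and `start` is given, optimise from that
#'   single start only (used by bootstrap refits, which restart from the
#'   point estimate); the full deterministic start set is used as a
#'   fallback if the single start fails.
#' @param reltol Convergence tolerance on the objective.
#'
#' @return An object of class `twl_fit`: family, `shape`, `scale`,
#'   `loglik` (weighted truncated log-likelihood), `aicc`, `n`, `mode_m`,
#'   `reliable`, plus the data and plot used.  Methods: [tidy()],
#'   [glance()], [autoplot()].
#'
#' @examples
#' plot <- square_plot(40)
#' d <- dist_quantile(runif(100, 0, 0.95), "gompertz", 0.0728, 0.0094)
#' fit <- twl_fit(d, "gompertz", plot)
#' glance(fit)
#' @export
twl_fit <- function(data, family, plot = square_plot(), treatment = NULL,
                    start = NULL, multistart = TRUE, reltol = 1e-8) {
  check_family(family)
  check_plot(plot)
  d <- extract_distances(data)
  tau <- plot$truncation_distance
  k <- dist_n_params(family)
  n <- length(d)
  if (n == 0) abort("No distances to fit.", class = "curtailr_data_error")
  if (any(d < 0) || any(d >= tau)) {
    abort("All distances must lie in [0, truncation distance).",
          class = "curtailr_data_error")
  }
  if (n < k + 2) {
    abort(sprintf(
      "Need at least %d observations to fit a %d-parameter family (got %d).",
      k + 2, k, n
    ), class = "curtailr_insufficient_data")
  }

  psi <- circle_inclusion_fraction(d, plot)
  w <- 1 / pmax(psi, 1e-12)
  w <- w * n / sum(w)

  negll <- function(theta) {
    par <- opt_to_par(family, theta)
    f <- suppressWarnings(dist_density(d, family, par$shape, par$scale))
    Ftau <- suppressWarnings(dist_cdf(tau, family, par$shape, par$scale))
    if (any(!is.finite(f)) || any(f <= 0) || !is.finite(Ftau) || Ftau <= 0) {
      return(1e10)
    }
    -sum(w * (log(f) - log(Ftau)))
  }

  starts <- family_starts(family, d)
  if (!is.null(start)) {
    th_start <- if (family == "rayleigh") par_to_opt(family, NA_real_, start[length(start)])
                else par_to_opt(family, start[1], start[2])
    # single-start mode: optimise from the supplied start only, keeping
    # the deterministic start set as a fallback if that fails
    starts <- if (multistart) c(list(th_start), starts)
              else list(th_start)
  }
  try_starts <- function(start_list) {
    best <- NULL
    for (th0 in start_list) {
      res <- tryCatch(
        optim(th0, negll, method = "BFGS",
              control = list(reltol = reltol, maxit = 500)),
        error = function(e) NULL
      )
      if (is.null(res) || !is.finite(res$value) || res$value >= 1e10) next
      if (is.null(best) || res$value < best$value) best <- res
    }
    best
  }
  best <- try_starts(starts)
  if (is.null(best) && !multistart) {
    best <- try_starts(family_starts(family, d))
  }
  if (is.null(best)) {
    abort(sprintf("TWL optimisation failed to converge for family '%s'.",
                  family),
          class = "curtailr_fit_error")
  }

  par <- opt_to_par(family, best$par)
  loglik <- -best$value
  aicc <- -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  mode_m <- dist_mode(family, par$shape, par$scale)
  # Degenerate when the mode is pushed to the truncation bound or the
  # optimiser ran into the parameter-scale boundary.
  at_bound <- any(abs(best$par) > 25)
  reliable <- is.finite(aicc) && mode_m < 0.95 * tau && !at_bound

  structure(
    list(
      family = family, shape = par$shape, scale = par$scale,
      loglik = loglik, aicc = aicc, n = n, mode_m = mode_m,
      reliable = reliable, treatment = treatment,
      distances = d, weights = w, plot = plot,
      convergence = best$convergence
    ),
    class = "twl_fit"
  )
}

extract_distances <- function(data) {
  if (is.data.frame(data)) {
    if (!"distance_m" %in% names(data)) {
      abort("`data` must contain a `distance_m` column.",
            class = "curtailr_data_error")
    }
    as.numeric(data$distance_m)
  } else {
    as.numeric(data)
  }
}

#' @export
print.twl_fit <- function(x, ...) {
  cat(sprintf(
    "<twl_fit> %s%s: shape = %s, scale = %.5g (n = %d, AICc = %.2f)\n",
    x$family,
    if (!is.null(x$treatment)) paste0(" [", x$treatment, "]") else "",
    if (is.na(x$shape)) "-" else sprintf("%.5g", x$shape),
    x$scale, x$n, x$aicc
  ))
  cat(sprintf("  mode %.1f m; %s\n", x$mode_m,
              if (x$reliable) "reliable" else "UNRELIABLE"))
  invisible(x)
}

#' Fit all candidate distance families to one sample
#'
#' Runs [twl_fit()] for each requested family, tolerating individual
#' fit failures (failed families are dropped with a warning).
#'
#' @inheritParams twl_fit
#' @param families Character vector of family names to try.
#' @return A list of `twl_fit` objects, named by family.
#' @export
fit_carcass_distances <- function(data, plot = square_plot(),
                                  families = distance_families(),
                                  treatment = NULL) {
  fits <- list()
  for (fam in families) {
    fit <- tryCatch(
      twl_fit(data, fam, plot, treatment = treatment),
      error = function(e) {
        warn(sprintf("Family '%s' failed to fit: %s", fam,
                     conditionMessage(e)))
        NULL
      }
    )
    if (!is.null(fit)) fits[[fam]] <- fit
  }
  fits
}

#' Select the best fit by AICc
#'
#' Chooses the reliable fit with the smallest AICc.  Ties are broken in
#' favour of fewer parameters, then alphabetically by family name.
#'
#' @param fits A list of fitted model objects carrying `aicc`,
#'   `reliable`, and `family` fields ([twl_fit()] or
#'   [fit_persistence()] results).
#' @return The selected fit object.
#' @export
select_by_aicc <- function(fits) {
  if (length(fits) == 0) {
    abort("No fits supplied.", class = "curtailr_selection_error")
  }
  rel <- Filter(function(f) isTRUE(f$reliable), fits)
  if (length(rel) == 0) {
    abort(paste(
      "All candidate fits are unreliable: the truncated sample does not",
      "cover the mode of the distance distribution. Pool this sample with",
      "a neighbouring treatment (`pool_distance_samples()`) and refit."
    ), class = "curtailr_selection_error")
  }
  aicc <- vapply(rel, function(f) f$aicc, numeric(1))
  npar <- vapply(rel, function(f) {
    if (inherits(f, "twl_fit")) dist_n_params(f$family) else f$n_params
  }, numeric(1))
  fam <- vapply(rel, function(f) f$family, character(1))
  ord <- order(aicc, npar, fam)
  rel[[ord[1]]]
}

#' @rdname select_by_aicc
#' @export
select_distance_model <- function(fits) {
  fit <- select_by_aicc(fits)
  if (!inherits(fit, "twl_fit")) {
    abort("`fits` must be `twl_fit` objects.")
  }
  fit
}

#' Pool carcass distance samples across treatments
#'
#' When a treatment's truncated distance sample does not include the
#' distribution mode (all its fits are unreliable), its distances can be
#' pooled with those of a neighbouring treatment and the pooled sample
#' fitted instead.  The pooled sample records its sources.
#'
#' @param ... Data frames with `distance_m` (and optionally `treatment`)
#'   columns, or numeric distance vectors.
#' @param label Label for the pooled sample.
#' @return A tibble with columns `distance_m`, `treatment` (the new
#'   label) and `source` (the original treatment or input index).
#' @examples
#' pool_distance_samples(
#'   tibble::tibble(distance_m = c(10, 20), treatment = "WOC"),
#'   tibble::tibble(distance_m = 30, treatment = "TIMR"),
#'   label = "TIMR + WOC"
#' )
#' @export
pool_distance_samples <- function(..., label = "pooled") {
  inputs <- list(...)
  if (length(inputs) < 1) abort("Supply at least one sample.")
  parts <- purrr::imap(inputs, function(x, i) {
    if (is.data.frame(x)) {
      src <- if ("treatment" %in% names(x)) as.character(x$treatment)
             else rep(as.character(i), nrow(x))
      tibble::tibble(distance_m = as.numeric(x$distance_m), source = src)
    } else {
      tibble::tibble(distance_m = as.numeric(x),
                     source = rep(as.character(i), length(x)))
    }
  })
  dplyr::bind_rows(parts) |>
    dplyr::mutate(treatment = label, .after = "distance_m")
}
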