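#' Area correction from a fitted distance distribution
#'
#' The area correction (AC) is the fraction of all carcasses expected to
#' fall within the searched part of the plot: the fitted distance
#' density's predicted carcass fraction in each 1-m annulus, multiplied
#' by the searched fraction of that annulus, summed from the turbine base
#' to the plot corner.  Carcass counts are divided by `g_search * AC`, so
#' AC converts "fatalities in the searched area" to "all fatalities".
#'
#' The predicted fraction uses the *untruncated* fitted CDF, so AC lies
#' between `F(a)` (everything inside the fully-searched radius) and
#' `F(tau)` (everything inside the corner distance).
#'
#' @param fit A [twl_fit()] object, or a list with `family`, `shape`,
#'   `scale` fields.
#' @param plot A [square_plot()].
#' @param annulus_width Annulus width in metres (default 1, matching the
#'   1-m annuli of the estimator definition).
#' @param force Compute even when `fit$reliable` is `FALSE`.  Unreliable
#'   fits produce area corrections that are artefacts of the truncation,
#'   so this is refused by default; pool samples instead.
#' @return The area correction, a proportion in `[0, 1]`.
#' @examples
#' plot <- square_plot(40)
#' fit <- list(family = "gompertz", shape = 0.0728, scale = 0.0094,
#'             reliable = TRUE)
#' area_correction(fit, plot)
#' @export
area_correction <- function(fit, plot = square_plot(), annulus_width = 1,
                            force = FALSE) {
  check_plot(plot)
  if (!force && !isTRUE(fit$reliable)) {
    abort(paste(
      "Refusing to compute an area correction from an unreliable fit;",
      "pool distance samples and refit, or use `force = TRUE`."
    ), class = "curtailr_unreliable_fit")
  }
  ann <- annulus_table(plot, width = annulus_width)
  Fhi <- dist_cdf(ann$d_hi, fit$family, fit$shape, fit$scale)
  Flo <- dist_cdf(ann$d_lo, fit$family, fit$shape, fit$scale)
  sum((Fhi - Flo) * ann$searched_fraction)
}

#' Bootstrap confidence interval for the area correction
#'
#' Resamples carcass distances with replacement, refits the *same*
#' family as the point estimate by truncated weighted likelihood, and
#' recomputes the area correction, giving a percentile confidence
#' interval.  Replicates whose refit fails to converge or is unreliable
#' are dropped and counted.
#'
#' @inheritParams twl_fit
#' @param family Family to fit (typically the AICc-selected family of
#'   the point estimate).
#' @param n_boot Number of bootstrap replicates (1000 in the standard
#'   analysis).
#' @param ci_level Confidence level (default 0.90).
#' @param seed Integer seed; replicate seeds are derived by a counter so
#'   results are reproducible.
#' @return An object of class `area_correction_ci`: a list with
#'   `estimate`, `ci_lower`, `ci_upper`, `n_bootstrap` (successful
#'   replicates), `n_failed`, `family`, `ci_level`.
#' @export
bootstrap_area_correction <- function(data, family, plot = square_plot(),
                                      n_boot = 1000, ci_level = 0.90,
                                      seed = 1) {
  d <- extract_distances(data)
  fit <- twl_fit(d, family, plot)
  est <- area_correction(fit, plot, force = TRUE)

  reps <- boot_area_correction_reps(d, fit, plot, n_boot, seed)
  ok <- reps[!is.na(reps)]
  n_failed <- sum(is.na(reps))
  if (n_failed > 0.2 * n_boot) {
    warn(sprintf(
      "%d of %d area-correction bootstrap replicates failed; CI may be unstable.",
      n_failed, n_boot
    ))
  }
  alpha <- (1 - ci_level) / 2
  ci <- unname(quantile(ok, c(alpha, 1 - alpha), type = 7))
  structure(
    list(
      estimate = est, ci_lower = ci[1], ci_upper = ci[2],
      n_bootstrap = length(ok), n_failed = n_failed,
      family = family, ci_level = ci_level, reliable = fit$reliable
    ),
    class = "area_correction_ci"
  )
}

# One vector of bootstrap AC replicates (NA where the refit failed or
# was unreliable).  Each replicate reseeds deterministically from
# seed + counter so subsets reproduce.
boot_area_correction_reps <- function(d, point_fit, plot, n_boot, seed) {
  vapply(seq_len(n_boot), function(b) {
    set.seed((seed + b) %% .Machine$integer.max)
    db <- sample(d, length(d), replace = TRUE)
    fit_b <- tryCatch(
      twl_fit(db, point_fit$family, plot,
              start = c(point_fit$shape, point_fit$scale), multistart = FALSE),
      error = function(e) NULL
    )
    if (is.null(fit_b) || !fit_b$reliable) return(NA_real_)
    area_correction(fit_b, plot, force = TRUE)
  }, numeric(1))
}

#' @export
print.area_correction_ci <- function(x, ...) {
  cat(sprintf(
    "<area_correction> %.3f (%.0f%% CI %.3f, %.3f) [%s; %d replicates, %d failed]\n",
    x$estimate, 100 * x$ci_level, x$ci_lower, x$ci_upper,
    x$family, x$n_bootstrap, x$n_failed
  ))
  invisible(x)
}
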