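#' Tidy and glance methods for fitted objects
#'
#' broom-style accessors: `tidy()` returns one row per parameter,
#' `glance()` a one-row model summary.
#'
#' @param x A fitted object.
#' @param ... Unused.
#' @return A tibble.
#' @name curtailr-tidiers
NULL

#' @rdname curtailr-tidiers
#' @method tidy twl_fit
#' @export
tidy.twl_fit <- function(x, ...) {
  tibble::tibble(
    term = c("shape", "scale"),
    estimate = c(x$shape, x$scale)
  ) |>
    dplyr::filter(!is.na(.data$estimate))
}

#' @rdname curtailr-tidiers
#' @method glance twl_fit
#' @export
glance.twl_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family,
    treatment = x$treatment %||% NA_character_,
    n = x$n,
    shape = x$shape,
    scale = x$scale,
    logLik = x$loglik,
    AICc = x$aicc,
    mode_m = x$mode_m,
    reliable = x$reliable
  )
}

#' @rdname curtailr-tidiers
#' @method tidy persistence_fit
#' @export
tidy.persistence_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params), estimate = unname(x$params))
}

#' @rdname curtailr-tidiers
#' @method glance persistence_fit
#' @export
glance.persistence_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family,
    n = x$n,
    logLik = x$loglik,
    AICc = x$aicc,
    median_days = x$median_days
  )
}

#' @rdname curtailr-tidiers
#' @method tidy seef_estimate
#' @export
tidy.seef_estimate <- function(x, ...) {
  tibble::tibble(
    term = c("p", "k"),
    estimate = c(x$p, x$k),
    ci_lower = c(x$ci_lower, NA_real_),
    ci_upper = c(x$ci_upper, NA_real_)
  )
}

#' @rdname curtailr-tidiers
#' @method tidy area_correction_ci
#' @export
tidy.area_correction_ci <- function(x, ...) {
  tibble::tibble(
    family = x$family,
    estimate = x$estimate,
    ci_lower = x$ci_lower,
    ci_upper = x$ci_upper,
    n_bootstrap = x$n_bootstrap,
    n_failed = x$n_failed
  )
}

#' @rdname curtailr-tidiers
#' @method tidy fatality_study
#' @export
tidy.fatality_study <- function(x, ...) {
  x$estimates
}

#' @rdname curtailr-tidiers
#' @method glance fatality_study
#' @export
glance.fatality_study <- function(x, ...) {
  tibble::tibble(
    p = x$seef$p,
    k = x$k,
    persistence_family = x$persistence$family,
    persistence_median_days = x$persistence$median_days,
    g_search = x$g_search,
    n_boot = x$n_boot,
    n_boot_failed = max(x$n_boot_failed),
    ci_level = x$ci_level
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
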