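#' Searcher efficiency from single-search bias trials
#'
#' Searcher efficiency (SEEF) is the probability `p` that a searcher
#' finds a carcass present in the searched area on a single search.  It
#' is estimated as the proportion of trial carcasses found among those
#' still *available* (not scavenged or otherwise removed before the
#' search); unavailable carcasses are excluded.  Single-search trials
#' cannot identify the detection decay factor `k` (the multiplicative
#' drop in detectability on each later search: `p`, `pk`, `pk^2`, ...),
#' so `k` is supplied, not estimated, and should be varied in a
#' sensitivity sweep.
#'
#' The confidence interval is the Wilson score interval.
#'
#' @param data A data frame of trial carcasses with logical columns
#'   `available` and `found` (`found` implies `available`).
#' @param ci_level Confidence level (default 0.90).
#' @param k Detection decay factor in `[0, 1]`, attached to the
#'   estimate for downstream use (default 0.67).
#' @return An object of class `seef_estimate`: `p`, `ci_lower`,
#'   `ci_upper`, `k`, `n_available`, `n_found`, `ci_level`.
#' @examples
#' trials <- tibble::tibble(available = rep(TRUE, 50),
#'                          found = rep(c(TRUE, FALSE), c(30, 20)))
#' estimate_seef(trials)
#' @export
estimate_seef <- function(data, ci_level = 0.90, k = 0.67) {
  if (!all(c("available", "found") %in% names(data))) {
    abort("`data` must have `available` and `found` columns.",
          class = "curtailr_data_error")
  }
  if (any(data$found & !data$available)) {
    abort("A carcass cannot be found but unavailable.",
          class = "curtailr_data_error")
  }
  if (!is.numeric(k) || k < 0 || k > 1) abort("`k` must be in [0, 1].")
  n_avail <- sum(data$available)
  if (n_avail == 0) {
    abort("No available trial carcasses; p is not estimable.",
          class = "curtailr_estimation_error")
  }
  n_found <- sum(data$found)
  p <- n_found / n_avail
  ci <- wilson_ci(n_found, n_avail, ci_level)
  structure(
    list(p = p, ci_lower = ci[1], ci_upper = ci[2], k = k,
         n_available = n_avail, n_found = n_found, ci_level = ci_level),
    class = "seef_estimate"
  )
}

# Wilson score interval for a binomial proportion.
wilson_ci <- function(x, n, level = 0.90) {
  z <- qnorm(1 - (1 - level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  # exact endpoints at the boundaries (guards floating-point round-off)
  lower <- if (x == 0) 0 else max(0, centre - half)
  upper <- if (x == n) 1 else min(1, centre + half)
  c(lower, upper)
}

#' @export
print.seef_estimate <- function(x, ...) {
  cat(sprintf(
    "<seef_estimate> p = %.3f (%.0f%% CI %.3f, %.3f), %d found of %d available; k = %.2f\n",
    x$p, 100 * x$ci_level, x$ci_lower, x$ci_upper,
    x$n_found, x$n_available, x$k
  ))
  invisible(x)
}

#' Searcher efficiency at the m-th search
#'
#' A carcass missed on earlier searches becomes harder to find; on the
#' `m`-th search after arrival the per-search detection probability is
#' `p * k^(m - 1)`.
#'
#' @param p Searcher efficiency on the first search, in `[0, 1]`.
#' @param k Detection decay factor in `[0, 1]`.
#' @param m Search index (1 = first search after arrival).  Vectorised.
#' @return Detection probability/ies.
#' @examples
#' seef_at_search(0.6, 0.7, 1:3)
#' @export
seef_at_search <- function(p, k, m) {
  if (any(p < 0 | p > 1) || any(k < 0 | k > 1)) {
    abort("`p` and `k` must be in [0, 1].")
  }
  if (any(m < 1 | m != round(m))) abort("`m` must be integer >= 1.")
  p * k^(m - 1)
}
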