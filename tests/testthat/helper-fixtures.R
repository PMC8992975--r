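# Shared fixture builders (all generated in code; no stored data).

make_seef_trials <- function(n_found, n_available, n_unavailable = 0) {
  tibble::tibble(
    available = rep(c(TRUE, FALSE), c(n_available, n_unavailable)),
    found = rep(c(TRUE, FALSE, FALSE),
                c(n_found, n_available - n_found, n_unavailable))
  )
}

# Interval-censor removal times through a check schedule (days).
censor_through_checks <- function(times, checks = c(1, 2, 3, 4, 7, 10, 14,
                                                    20, 30)) {
  horizon <- max(checks)
  purrr::map_dfr(times, function(t) {
    if (t > horizon) {
      tibble::tibble(last_present_d = horizon, first_absent_d = NA_real_,
                     censored = TRUE)
    } else {
      before <- checks[checks < t]
      tibble::tibble(
        last_present_d = if (length(before)) max(before) else 0,
        first_absent_d = min(checks[checks >= t]),
        censored = FALSE
      )
    }
  })
}

# Distances observed on a square plot: draw from a family, thin by the
# plot geometry (uniform bearing), keep those inside.
sample_plot_distances <- function(n_target, family, shape, scale,
                                  plot = square_plot(), seed = 1) {
  set.seed(seed)
  out <- numeric(0)
  while (length(out) < n_target) {
    d <- dist_quantile(runif(2 * n_target), family, shape, scale)
    th <- runif(2 * n_target, 0, 2 * pi)
    keep <- abs(d * cos(th)) <= plot$half_width &
      abs(d * sin(th)) <= plot$half_width
    out <- c(out, d[keep])
  }
  out[seq_len(n_target)]
}

# Minimal persistence_fit stand-ins with known parameters.
fake_persistence <- function(family, params) {
  structure(list(family = family, params = params), class = "persistence_fit")
}
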