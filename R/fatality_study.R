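#' Full detection-adjusted fatality analysis with paired bootstrap
#'
#' Runs the complete fatality-estimation chain for a multi-treatment
#' carcass study: searcher efficiency, AICc-selected carcass
#' persistence, AICc-selected truncated-weighted-likelihood distance
#' fits with per-treatment area corrections (pooling a treatment's
#' distances with a partner's when its truncated sample does not cover
#' the distribution mode), season-level detection probability, and
#' Horvitz-Thompson adjusted fatality estimates per turbine and per MW.
#'
#' Uncertainty is propagated by a nonparametric bootstrap that, in each
#' replicate, resamples searcher-efficiency trials, persistence-trial
#' carcasses, carcass distances (per treatment), and per-turbine carcass
#' counts, then recomputes every estimate.  Replicates are *paired*
#' across treatments (they share the searcher-efficiency and persistence
#' resamples), so confidence intervals for treatment comparisons respect
#' the correlation between the control and treatment estimates.
#' Comparisons between estimates use the CI-overlap rule
#' ([ci_overlap_distinct()]).
#'
#' @param carcasses Data frame of carcasses found on search plots:
#'   columns `turbine_id`, `treatment`, `distance_m`, and optionally
#'   logical `inside_plot` (records with `inside_plot = FALSE` are
#'   excluded from estimation).
#' @param seef_trials Searcher-efficiency trial data (see
#'   [estimate_seef()]).
#' @param persistence_trials Persistence trial data (see
#'   [fit_persistence()]).
#' @param plot A [square_plot()].
#' @param k Detection decay factor (see [estimate_seef()]).
#' @param control Name of the control treatment.
#' @param pool Named character vector of pooling directives, e.g.
#'   `c(TIMR = "WOC")`: if all of TIMR's distance fits are unreliable,
#'   its distances are pooled with WOC's and the pooled sample fitted.
#' @param n_turbines Turbines per treatment group: a single number or a
#'   vector named by treatment.
#' @param capacity_mw Turbine capacity in MW.
#' @param n_boot Bootstrap replicates.
#' @param ci_level Confidence level for all intervals.
#' @param seed Integer seed (replicate streams derived by counter).
#' @param search_offsets,n_searches,interval_days Search schedule passed
#'   to [detection_probability()].
#' @param dist_families,pers_families Candidate distance and persistence
#'   families.
#'
#' @return An object of class `fatality_study`: a list with elements
#'   `seef`, `persistence` (selected fit), `persistence_fits`,
#'   `distance` (per-treatment list with all fits, the selected fit,
#'   `pooled` flag and area correction), `g_search`, `estimates` (tibble
#'   mirroring an observed/adjusted fatality table with CIs),
#'   `comparisons` (reductions vs control with CIs and distinctness),
#'   `reduction_ratios`, `n_boot`, `n_boot_failed`, `warnings`.
#' @export
estimate_study_fatalities <- function(carcasses, seef_trials,
                                      persistence_trials,
                                      plot = square_plot(),
                                      k = 0.67,
                                      control = "control",
                                      pool = NULL,
                                      n_turbines = 10,
                                      capacity_mw = 1.65,
                                      n_boot = 1000,
                                      ci_level = 0.90,
                                      seed = 1,
                                      search_offsets = NULL,
                                      n_searches = 78,
                                      interval_days = 1,
                                      dist_families = distance_families(),
                                      pers_families = c("exponential",
                                                        "weibull",
                                                        "lognormal",
                                                        "loglogistic")) {
  warnings <- character()
  carcasses <- tibble::as_tibble(carcasses)
  if (!"inside_plot" %in% names(carcasses)) carcasses$inside_plot <- TRUE
  n_off <- sum(!carcasses$inside_plot)
  if (n_off > 0) {
    warnings <- c(warnings, sprintf(
      "%d carcass(es) found outside search plots excluded from estimation.",
      n_off
    ))
  }
  carcasses <- dplyr::filter(carcasses, .data$inside_plot)
  treatments <- unique(as.character(carcasses$treatment))
  if (!control %in% treatments) {
    abort(sprintf("Control treatment '%s' not present in `carcasses`.",
                  control), class = "curtailr_data_error")
  }
  treatments <- c(control, setdiff(treatments, control))
  nt <- turbine_counts(n_turbines, treatments)

  # --- point estimates ------------------------------------------------
  seef <- estimate_seef(seef_trials, ci_level = ci_level, k = k)
  pers_fits <- fit_persistence_models(persistence_trials,
                                      families = pers_families)
  pers <- select_persistence_model(pers_fits)

  distance <- lapply(treatments, function(tr) {
    d_tr <- carcasses$distance_m[carcasses$treatment == tr]
    fit_treatment_distances(d_tr, tr, carcasses, plot, pool,
                            dist_families)
  })
  names(distance) <- treatments
  for (tr in treatments) {
    if (distance[[tr]]$pooled) {
      warnings <- c(warnings, sprintf(
        "Treatment '%s': distance fit unreliable; %s '%s'.",
        tr,
        if (distance[[tr]]$inherited) "fit inherited from" else "pooled with",
        distance[[tr]]$pooled_with
      ))
    }
  }

  g <- detection_probability(seef, pers, search_offsets = search_offsets,
                             n_searches = n_searches,
                             interval_days = interval_days)

  counts <- vapply(treatments, function(tr) {
    sum(carcasses$treatment == tr)
  }, numeric(1))
  acs <- vapply(treatments, function(tr) {
    area_correction(distance[[tr]]$selected, plot, force = TRUE)
  }, numeric(1))

  est <- purrr::map_dfr(treatments, function(tr) {
    estimate_fatalities(counts[[tr]], g, acs[[tr]], nt[[tr]],
                        capacity_mw = capacity_mw, treatment = tr)
  })

  # --- paired bootstrap -----------------------------------------------
  per_turbine <- lapply(treatments, function(tr) {
    tab <- table(factor(
      carcasses$turbine_id[carcasses$treatment == tr],
      levels = unique(carcasses$turbine_id[carcasses$treatment == tr])
    ))
    # turbines with zero carcasses still contribute resampling mass
    c(as.numeric(tab), rep(0, max(0, nt[[tr]] - length(tab))))
  })
  names(per_turbine) <- treatments

  m_reps <- matrix(NA_real_, nrow = n_boot, ncol = length(treatments),
                   dimnames = list(NULL, treatments))
  ac_reps <- m_reps
  for (b in seq_len(n_boot)) {
    set.seed((seed + b) %% .Machine$integer.max)
    rep_b <- bootstrap_replicate(carcasses, seef_trials, persistence_trials,
                                 seef, pers, distance, treatments, plot, k,
                                 nt, per_turbine, search_offsets, n_searches,
                                 interval_days)
    if (!is.null(rep_b)) {
      m_reps[b, ] <- rep_b$m
      ac_reps[b, ] <- rep_b$ac
    }
  }
  # Replicates are used pairwise-complete: a failed distance refit for
  # one treatment (dropped and counted, as in the AC bootstrap) does not
  # discard the other treatments' draws in that replicate.
  n_failed <- colSums(is.na(m_reps))
  for (tr in treatments) {
    if (n_failed[[tr]] > 0.2 * n_boot) {
      warnings <- c(warnings, sprintf(
        "Treatment '%s': %d of %d bootstrap replicates failed.",
        tr, n_failed[[tr]], n_boot
      ))
    }
  }
  alpha <- (1 - ci_level) / 2
  ci <- apply(m_reps, 2, quantile, probs = c(alpha, 1 - alpha),
              na.rm = TRUE)

  est <- est |>
    dplyr::mutate(
      m_ci_lower = ci[1, .data$treatment],
      m_ci_upper = ci[2, .data$treatment],
      m_mw_ci_lower = .data$m_ci_lower / capacity_mw,
      m_mw_ci_upper = .data$m_ci_upper / capacity_mw
    )

  # --- comparisons ----------------------------------------------------
  others <- setdiff(treatments, control)
  comparisons <- purrr::map_dfr(others, function(tr) {
    pair_ok <- !is.na(m_reps[, control]) & !is.na(m_reps[, tr])
    red_reps <- fatality_reduction(m_reps[pair_ok, control],
                                   m_reps[pair_ok, tr])
    red_ci <- quantile(red_reps, c(alpha, 1 - alpha))
    tibble::tibble(
      comparison = paste(control, "vs", tr),
      treatment = tr,
      reduction = fatality_reduction(
        est$m_per_turbine[est$treatment == control],
        est$m_per_turbine[est$treatment == tr]
      ),
      ci_lower = red_ci[[1]],
      ci_upper = red_ci[[2]],
      distinct = ci_overlap_distinct(
        c(est$m_ci_lower[est$treatment == control],
          est$m_ci_upper[est$treatment == control]),
        c(est$m_ci_lower[est$treatment == tr],
          est$m_ci_upper[est$treatment == tr])
      )
    )
  })

  ratios <- NULL
  if (length(others) >= 2) {
    pairs <- expand.grid(t1 = others, t2 = others,
                         stringsAsFactors = FALSE) |>
      dplyr::filter(.data$t1 != .data$t2)
    ratios <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
      t1 <- pairs$t1[i]; t2 <- pairs$t2[i]
      trio_ok <- !is.na(m_reps[, control]) & !is.na(m_reps[, t1]) &
        !is.na(m_reps[, t2]) & m_reps[, control] != m_reps[, t2]
      rr_reps <- reduction_ratio(m_reps[trio_ok, control],
                                 m_reps[trio_ok, t1], m_reps[trio_ok, t2])
      rr_ci <- quantile(rr_reps, c(alpha, 1 - alpha))
      tibble::tibble(
        comparison = paste(t1, "vs", t2),
        ratio = reduction_ratio(
          est$m_per_turbine[est$treatment == control],
          est$m_per_turbine[est$treatment == t1],
          est$m_per_turbine[est$treatment == t2]
        ),
        ci_lower = rr_ci[[1]],
        ci_upper = rr_ci[[2]]
      )
    })
  }

  structure(
    list(
      seef = seef, persistence = pers, persistence_fits = pers_fits,
      distance = distance, g_search = g, estimates = est,
      comparisons = comparisons, reduction_ratios = ratios,
      ac_replicates = ac_reps,
      m_replicates = m_reps,
      n_boot = n_boot, n_boot_failed = n_failed,
      ci_level = ci_level, k = k, seed = seed,
      control = control, warnings = warnings
    ),
    class = "fatality_study"
  )
}

turbine_counts <- function(n_turbines, treatments) {
  if (length(n_turbines) == 1 && is.null(names(n_turbines))) {
    return(setNames(rep(n_turbines, length(treatments)), treatments))
  }
  if (!all(treatments %in% names(n_turbines))) {
    abort("`n_turbines` must name every treatment.",
          class = "curtailr_data_error")
  }
  n_turbines[treatments]
}

# Fit all candidate families to one treatment's distances, selecting by
# AICc; fall back to pooling with the directed partner when no fit is
# reliable (or the sample is too small to fit at all).
fit_treatment_distances <- function(d_tr, tr, carcasses, plot, pool,
                                    families) {
  attempt <- function(d) {
    fits <- suppressWarnings(
      fit_carcass_distances(d, plot, families = families, treatment = tr)
    )
    list(fits = fits,
         selected = tryCatch(select_distance_model(fits),
                             error = function(e) NULL))
  }
  own <- attempt(d_tr)
  if (!is.null(own$selected)) {
    return(list(fits = own$fits, selected = own$selected,
                distances = d_tr, pooled = FALSE,
                pooled_with = NA_character_, inherited = FALSE))
  }
  partner <- if (!is.null(pool) && tr %in% names(pool)) pool[[tr]] else NULL
  if (is.null(partner)) {
    abort(sprintf(
      "No reliable distance fit for treatment '%s' and no pooling directive.",
      tr
    ), class = "curtailr_selection_error")
  }
  d_partner <- carcasses$distance_m[carcasses$treatment == partner]
  d_pool <- c(d_tr, d_partner)
  pooled <- attempt(d_pool)
  if (!is.null(pooled$selected)) {
    return(list(fits = pooled$fits, selected = pooled$selected,
                distances = d_pool, pooled = TRUE, pooled_with = partner,
                inherited = FALSE))
  }
  # Last resort: the pooled sample is still dominated by the truncation
  # (mass increasing to the corner distance), so fall back to the
  # partner's own distance model.  The resulting area correction is, if
  # anything, too high, making the treatment's adjusted fatality a lower
  # bound.
  own_partner <- attempt(d_partner)
  if (is.null(own_partner$selected)) {
    abort(sprintf(
      "No reliable distance fit for treatment '%s' even after pooling with '%s'.",
      tr, partner
    ), class = "curtailr_selection_error")
  }
  list(fits = own_partner$fits, selected = own_partner$selected,
       distances = d_partner, pooled = TRUE, pooled_with = partner,
       inherited = TRUE)
}

# One paired bootstrap replicate; returns NULL on failure of any stage.
bootstrap_replicate <- function(carcasses, seef_trials, persistence_trials,
                                seef, pers, distance, treatments, plot, k,
                                nt, per_turbine, search_offsets, n_searches,
                                interval_days) {
  seef_b <- tryCatch({
    rows <- sample(nrow(seef_trials), replace = TRUE)
    estimate_seef(seef_trials[rows, ], k = k)
  }, error = function(e) NULL)
  if (is.null(seef_b)) return(NULL)

  pers_b <- tryCatch({
    rows <- sample(nrow(persistence_trials), replace = TRUE)
    fit_persistence(persistence_trials[rows, ], pers$family)
  }, error = function(e) NULL)
  if (is.null(pers_b)) return(NULL)

  g_b <- tryCatch(
    detection_probability(seef_b, pers_b, search_offsets = search_offsets,
                          n_searches = n_searches,
                          interval_days = interval_days),
    error = function(e) NULL
  )
  if (is.null(g_b)) return(NULL)

  ac_b <- setNames(rep(NA_real_, length(treatments)), treatments)
  for (tr in treatments) {
    sel <- distance[[tr]]$selected
    d <- distance[[tr]]$distances
    fit_b <- tryCatch(
      twl_fit(sample(d, length(d), replace = TRUE), sel$family, plot,
              start = c(sel$shape, sel$scale), multistart = FALSE),
      error = function(e) NULL
    )
    if (is.null(fit_b) || !fit_b$reliable) next  # this treatment's draw fails
    ac_b[tr] <- area_correction(fit_b, plot, force = TRUE)
  }

  m_b <- setNames(rep(NA_real_, length(treatments)), treatments)
  for (tr in treatments) {
    cnt <- sum(sample(per_turbine[[tr]], nt[[tr]], replace = TRUE))
    m_b[tr] <- cnt / (nt[[tr]] * g_b * ac_b[tr])
  }
  list(m = m_b, ac = ac_b)
}

#' @export
print.fatality_study <- function(x, ...) {
  cat(sprintf(
    "<fatality_study> %d treatments; p = %.2f, k = %.2f, %s persistence (median %.1f d), g_search = %.3f\n",
    nrow(x$estimates), x$seef$p, x$k, x$persistence$family,
    x$persistence$median_days, x$g_search
  ))
  print(x$estimates)
  if (!is.null(x$comparisons)) print(x$comparisons)
  if (length(x$warnings)) {
    cat("Warnings:\n")
    for (w in x$warnings) cat(" -", w, "\n")
  }
  invisible(x)
}
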