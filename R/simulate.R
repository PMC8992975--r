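#' Configuration for a synthetic curtailment fatality study
#'
#' Defines the ground truth of a simulated three-treatment carcass
#' study: true per-turbine fatality rates, carcass fall-distance
#' distributions, the carcass persistence distribution, searcher
#' efficiency, trial sizes, the search schedule, and the turbine
#' operation model (wind regime, power curve, curtailment rules).
#'
#' Defaults emulate a 78-night field season (July 15 - September 30)
#' with 10 turbines per treatment searched daily on 80 m x 80 m plots:
#' Gompertz fall distances with modes near 28 m (control), 37 m
#' (wind-speed-only curtailment, WOC) and 47 m (acoustic-informed
#' curtailment, TIMR); lognormal persistence with median 8.7 days and
#' log-sd 1.4 (daily persistence probability about 94%); searcher
#' efficiency 0.60 from 42 single-search trials; 56 persistence-trial
#' carcasses monitored to 30 days; true fatality rates chosen so the
#' expected observed counts are near 187/78/31; and a Weibull wind
#' regime with mean 5.7 m/s driving a 3.5 m/s cut-in, 13.5 m/s rated
#' power curve with WOC curtailment below 4.5 m/s and TIMR curtailment
#' below 8.0 m/s within 30 minutes of a simulated bat detection.
#'
#' @param seed Integer seed; all sub-streams derive from it.
#' @param n_turbines Turbines per treatment.
#' @param n_nights Season length in nights.
#' @param half_width Plot half-width, metres.
#' @param treatments Tibble with columns `treatment`, `rate` (true
#'   fatalities per turbine per season), `dist_family`, `dist_shape`,
#'   `dist_scale`.
#' @param persistence_meanlog,persistence_sdlog Lognormal removal-time
#'   parameters (days).
#' @param persistence_check_days Check schedule for persistence trials,
#'   days since placement; the last entry is the censoring horizon.
#' @param seef_p True searcher efficiency.
#' @param k True (and assumed) detection decay factor.
#' @param seef_available_prob Probability a placed trial carcass is
#'   still available (not scavenged) at its single search.
#' @param n_seef_trials,n_persistence_trials Trial sizes.
#' @param miss_search_prob Probability a planned daily search is missed.
#' @param wind_shape,wind_scale Weibull wind-speed parameters (m/s).
#' @param cut_in_mps,rated_mps,capacity_mw Power-curve parameters.
#' @param woc_threshold_mps,timr_threshold_mps Curtailment wind
#'   thresholds.
#' @param bat_prob0,bat_prob_wind_scale Per-10-minute bat-detection
#'   probability at zero wind and its exponential decay scale with wind
#'   speed (activity is higher in low wind).
#' @param bat_hold_bins Number of trailing 10-minute bins (including the
#'   current one) in which a detection keeps TIMR turbines curtailed;
#'   4 bins = a 30-minute hold.
#' @param price_per_mwh Market revenue rate.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_turbines = 10,
                       n_nights = 78,
                       half_width = 40,
                       treatments = tibble::tibble(
                         treatment = c("control", "WOC", "TIMR"),
                         rate = c(23.7, 12.3, 6.9),
                         dist_family = "gompertz",
                         dist_shape = c(0.0728, 0.0589, 0.0441),
                         dist_scale = c(0.0094, 0.0066, 0.0055)
                       ),
                       persistence_meanlog = log(8.7),
                       persistence_sdlog = 1.4,
                       persistence_check_days = c(1, 2, 3, 4, 7, 10, 14,
                                                  20, 30),
                       seef_p = 0.60,
                       k = 0.67,
                       seef_available_prob = 0.95,
                       n_seef_trials = 42,
                       n_persistence_trials = 56,
                       miss_search_prob = 0.02,
                       wind_shape = 2,
                       wind_scale = 5.7 / gamma(1.5),
                       cut_in_mps = 3.5,
                       rated_mps = 13.5,
                       capacity_mw = 1.65,
                       woc_threshold_mps = 4.5,
                       timr_threshold_mps = 8.0,
                       bat_prob0 = 0.33,
                       bat_prob_wind_scale = 8,
                       bat_hold_bins = 4,
                       price_per_mwh = 40) {
  cfg <- as.list(environment())
  stopifnot(
    all(cfg$treatments$rate >= 0),
    seef_p >= 0, seef_p <= 1, k >= 0, k <= 1,
    woc_threshold_mps > cut_in_mps, timr_threshold_mps > cut_in_mps
  )
  structure(cfg, class = "sim_config")
}

#' Simulate a complete carcass study with known ground truth
#'
#' Generates every data stream of a fatality study from the
#' configuration's true parameters: per-turbine nightly fatalities
#' (Poisson), fall positions (configured distance family, uniform
#' bearing, tested against the square plot), removal times, per-search
#' detection outcomes through the realised daily schedule (with missed
#' searches), searcher-efficiency trials and persistence trials observed
#' through the check schedule.  Deterministic given the seed.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_study`:
#' \describe{
#'   \item{carcasses}{Observed carcasses, formatted for
#'     [estimate_study_fatalities()] (all found carcasses fell inside
#'     plots).}
#'   \item{fatalities}{Every true fatality with fall position, removal
#'     time, and detection outcome.}
#'   \item{seef_trials, persistence_trials}{Trial tables.}
#'   \item{truth}{Per-treatment tibble of the true fatality rate, true
#'     area correction, analytic `g_search` (averaged over arrival
#'     nights of the finite season) and expected observed count.}
#' }
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  plot <- square_plot(cfg$half_width)
  a <- cfg$half_width

  set.seed(cfg$seed %% .Machine$integer.max)
  fatalities <- purrr::map_dfr(seq_len(nrow(cfg$treatments)), function(i) {
    tr <- cfg$treatments[i, ]
    purrr::map_dfr(seq_len(cfg$n_turbines), function(tb) {
      n_night <- rpois(cfg$n_nights, tr$rate / cfg$n_nights)
      n <- sum(n_night)
      if (n == 0) return(NULL)
      night <- rep(seq_len(cfg$n_nights), n_night)
      d <- dist_quantile(runif(n), tr$dist_family, tr$dist_shape,
                         tr$dist_scale)
      theta <- runif(n, 0, 2 * pi)
      removal <- rlnorm(n, cfg$persistence_meanlog, cfg$persistence_sdlog)
      tibble::tibble(
        treatment = tr$treatment,
        turbine_id = sprintf("%s_%02d", tr$treatment, tb),
        night = night,
        distance_m = d,
        x = d * cos(theta), y = d * sin(theta),
        inside_plot = abs(d * cos(theta)) <= a & abs(d * sin(theta)) <= a,
        arrival_frac = runif(n),
        removal_d = removal
      )
    })
  })

  if (nrow(fatalities) > 0) {
    fatalities$carcass_id <- sprintf("C%05d", seq_len(nrow(fatalities)))
    det <- purrr::pmap(
      list(fatalities$night, fatalities$arrival_frac, fatalities$removal_d,
           fatalities$inside_plot),
      function(night, u, removal, inside) {
        simulate_detection(night, u, removal, inside, cfg)
      }
    )
    fatalities$found <- vapply(det, function(x) x$found, logical(1))
    fatalities$search_found <- vapply(det, function(x) x$m, integer(1))
  } else {
    fatalities <- tibble::tibble(
      treatment = character(), turbine_id = character(), night = integer(),
      distance_m = numeric(), x = numeric(), y = numeric(),
      inside_plot = logical(), arrival_frac = numeric(),
      removal_d = numeric(), carcass_id = character(), found = logical(),
      search_found = integer()
    )
  }

  carcasses <- fatalities |>
    dplyr::filter(.data$found) |>
    dplyr::transmute(
      carcass_id = .data$carcass_id,
      turbine_id = .data$turbine_id,
      treatment = .data$treatment,
      night_found = .data$night + .data$search_found - 1L,
      distance_m = .data$distance_m,
      inside_plot = TRUE,
      scheduled_search = TRUE
    )

  set.seed((cfg$seed + 104729) %% .Machine$integer.max)
  avail <- runif(cfg$n_seef_trials) < cfg$seef_available_prob
  seef_trials <- tibble::tibble(
    carcass_id = sprintf("SEEF%03d", seq_len(cfg$n_seef_trials)),
    available = avail,
    found = avail & runif(cfg$n_seef_trials) < cfg$seef_p
  )

  set.seed((cfg$seed + 224737) %% .Machine$integer.max)
  t_remove <- rlnorm(cfg$n_persistence_trials, cfg$persistence_meanlog,
                     cfg$persistence_sdlog)
  checks <- cfg$persistence_check_days
  horizon <- max(checks)
  persistence_trials <- purrr::map_dfr(
    seq_len(cfg$n_persistence_trials),
    function(i) {
      t <- t_remove[i]
      if (t > horizon) {
        tibble::tibble(carcass_id = sprintf("PERS%03d", i),
                       last_present_d = horizon, first_absent_d = NA_real_,
                       censored = TRUE)
      } else {
        first_absent <- min(checks[checks >= t])
        before <- checks[checks < t]
        tibble::tibble(carcass_id = sprintf("PERS%03d", i),
                       last_present_d = if (length(before)) max(before) else 0,
                       first_absent_d = first_absent,
                       censored = FALSE)
      }
    }
  )

  truth <- purrr::map_dfr(seq_len(nrow(cfg$treatments)), function(i) {
    tr <- cfg$treatments[i, ]
    fit_true <- list(family = tr$dist_family, shape = tr$dist_shape,
                     scale = tr$dist_scale, reliable = TRUE)
    ac <- area_correction(fit_true, plot)
    S <- function(t) 1 - plnorm(t, cfg$persistence_meanlog,
                                cfg$persistence_sdlog)
    g <- mean(vapply(seq_len(cfg$n_nights), function(night) {
      detection_probability(
        list(p = cfg$seef_p * (1 - cfg$miss_search_prob), k = cfg$k), S,
        n_searches = cfg$n_nights - night + 1
      )
    }, numeric(1)))
    tibble::tibble(
      treatment = tr$treatment,
      true_m_per_turbine = tr$rate,
      true_ac = ac,
      true_g_search = g,
      true_g_total = g * ac,
      expected_observed = tr$rate * cfg$n_turbines * g * ac
    )
  })

  structure(
    list(carcasses = carcasses, fatalities = fatalities,
         seef_trials = seef_trials, persistence_trials = persistence_trials,
         truth = truth, config = cfg),
    class = "sim_study"
  )
}

# Per-carcass detection through the realised daily search schedule:
# searches happen on mornings night, night+1, ... until season end, each
# conducted with probability 1 - miss_search_prob; a carcass arriving at
# fraction u of its night persists (m - 1 + (1 - u)) days to the m-th
# morning, and is detected at decayed efficiency p k^(j-1) where j
# counts the conducted searches it survived to.
simulate_detection <- function(night, u, removal, inside, cfg) {
  if (!inside) return(list(found = FALSE, m = NA_integer_))
  n_searches <- cfg$n_nights - night + 1
  j <- 0L
  for (m in seq_len(n_searches)) {
    persist_to_m <- (m - 1) + (1 - u)
    if (removal < persist_to_m) break
    if (runif(1) < cfg$miss_search_prob) next  # search not conducted
    j <- j + 1L
    if (runif(1) < cfg$seef_p * cfg$k^(j - 1)) {
      return(list(found = TRUE, m = m))
    }
  }
  list(found = FALSE, m = NA_integer_)
}

#' Simulate 10-minute turbine operation records
#'
#' Generates a shared facility-level Weibull wind series with
#' multiplicative per-turbine noise, applies each treatment's
#' curtailment rule within the nightly treatment window (18:00-06:00
#' through August, 18:00-07:00 in September), and converts wind to
#' energy through a cubic power curve between cut-in and rated speed.
#' Curtailed bins produce no energy.  TIMR turbines are curtailed when
#' wind is below the TIMR threshold and a simulated bat detection
#' occurred within the hold window; bat detections are Bernoulli per bin
#' with probability decaying in wind speed.  Control turbines are never
#' curtailed.
#'
#' @param config A [sim_config()].
#' @return A tibble of 10-minute records: `turbine_id`, `treatment`,
#'   `timestamp`, `wind_speed_mps`, `in_treatment_window`, `curtailed`,
#'   `energy_mwh`.
#' @export
simulate_ops <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed((cfg$seed + 350377) %% .Machine$integer.max)

  start <- as.POSIXct("2015-07-15 00:00:00", tz = "UTC")
  ts <- seq(start, by = 600, length.out = cfg$n_nights * 144)
  hr <- as.integer(format(ts, "%H"))
  month <- as.integer(format(ts, "%m"))
  morning_cut <- ifelse(month >= 9, 7L, 6L)
  in_window <- hr >= 18 | hr < morning_cut

  base_wind <- rweibull(length(ts), cfg$wind_shape, cfg$wind_scale)
  # facility-level bat activity stream (shared across TIMR turbines)
  bat_prob <- pmin(1, cfg$bat_prob0 * exp(-base_wind / cfg$bat_prob_wind_scale))
  bat <- runif(length(ts)) < bat_prob
  bat_recent <- as.logical(stats::filter(as.numeric(bat),
                                         rep(1, cfg$bat_hold_bins),
                                         sides = 1))
  bat_recent[seq_len(cfg$bat_hold_bins - 1)] <-
    vapply(seq_len(cfg$bat_hold_bins - 1),
           function(i) any(bat[seq_len(i)]), logical(1))

  purrr::map_dfr(seq_len(nrow(cfg$treatments)), function(i) {
    tr <- cfg$treatments$treatment[i]
    purrr::map_dfr(seq_len(cfg$n_turbines), function(tb) {
      wind <- base_wind * exp(stats::rnorm(length(ts), 0, 0.05))
      curtailed <- switch(tr,
        control = rep(FALSE, length(ts)),
        WOC = in_window & wind < cfg$woc_threshold_mps,
        TIMR = in_window & wind < cfg$timr_threshold_mps & bat_recent,
        rep(FALSE, length(ts))
      )
      tibble::tibble(
        turbine_id = sprintf("%s_%02d", tr, tb),
        treatment = tr,
        timestamp = ts,
        wind_speed_mps = wind,
        in_treatment_window = in_window,
        curtailed = curtailed,
        energy_mwh = ifelse(curtailed, 0,
                            power_curve(wind, cfg) / 6)
      )
    })
  })
}

#' Turbine power curve
#'
#' Cubic interpolation between cut-in and rated wind speed: no output
#' below cut-in, nameplate capacity at and above rated speed.
#'
#' @param v Wind speed(s), m/s.
#' @param config A [sim_config()] supplying `cut_in_mps`, `rated_mps`,
#'   `capacity_mw`.
#' @return Power in MW.
#' @export
power_curve <- function(v, config = sim_config()) {
  ci <- config$cut_in_mps; r <- config$rated_mps; cap <- config$capacity_mw
  p <- cap * (pmin(pmax(v, ci), r)^3 - ci^3) / (r^3 - ci^3)
  pmax(p, 0)
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf(
    "<sim_study> %d true fatalities, %d observed carcasses; seed %d\n",
    nrow(x$fatalities), nrow(x$carcasses), x$config$seed
  ))
  print(x$truth)
  invisible(x)
}
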