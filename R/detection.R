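#' Season-level carcass detection probability within the searched area
#'
#' Combines searcher efficiency (`p` with decay `k`), the fitted carcass
#' persistence distribution, and the realised search schedule into the
#' probability `g_search` that a carcass falling in the searched area is
#' eventually found.  For a carcass arriving during the night before the
#' first subsequent search, the chance it is found on the `m`-th search
#' is the product of (i) persisting to that search, (ii) being missed on
#' every earlier search, and (iii) being detected at the decayed
#' efficiency `p k^(m-1)`:
#' \deqn{g = \sum_{m \ge 1} P(\mathrm{persist\ to\ search}\ m)\;
#'       p k^{m-1} \prod_{l=1}^{m-1} (1 - p k^{l-1}).}
#' With arrival uniform in the night and search offsets `t_m` (days
#' after the first search opportunity at `t_1`),
#' `P(persist to search m) = (1/I) * integral of S(t_m - t_1 + u) du`
#' over `u` in `(0, I)` with `I = t_1`.  Gaps in the schedule (missed
#' searches) simply lengthen the corresponding offsets.  The series is
#' truncated once a term falls below `tol`.
#'
#' @param seef A [estimate_seef()] result, or a list with `p` and `k`.
#' @param persistence A [fit_persistence()] result, or a function
#'   `S(t)` returning the persistence probability at `t` days.
#' @param search_offsets Numeric vector of search times in days since
#'   the start of the arrival night (strictly increasing, first > 0).
#'   Defaults to daily searches: `seq_len(n_searches) * interval_days`.
#' @param n_searches,interval_days Used to build the default daily
#'   schedule (a full 78-night season is effectively infinite for
#'   persistence on the order of days; the series truncates itself).
#' @param arrival `"uniform"` (carcass arrives uniformly in the interval
#'   preceding the first search) or `"point"` (arrival exactly at time
#'   0, so persistence is evaluated at the search times themselves).
#' @param tol Series truncation tolerance.
#' @return `g_search`, a probability in `(0, 1]`.
#' @examples
#' S <- function(t) exp(-0.2 * t)
#' detection_probability(list(p = 0.5, k = 0.8), S,
#'                       search_offsets = c(1, 2), arrival = "point")
#' @export
detection_probability <- function(seef, persistence,
                                  search_offsets = NULL,
                                  n_searches = 78, interval_days = 1,
                                  arrival = c("uniform", "point"),
                                  tol = 1e-10) {
  arrival <- match.arg(arrival)
  p <- if (inherits(seef, "seef_estimate") || is.list(seef)) seef$p else seef[1]
  k <- if (inherits(seef, "seef_estimate") || is.list(seef)) seef$k else seef[2]
  if (is.null(p) || is.null(k) || p < 0 || p > 1 || k < 0 || k > 1) {
    abort("`seef` must provide p and k in [0, 1].")
  }
  S <- if (is.function(persistence)) persistence
       else function(t) persistence_survival(persistence, t)
  if (is.null(search_offsets)) {
    search_offsets <- seq_len(n_searches) * interval_days
  }
  if (length(search_offsets) == 0 || any(diff(search_offsets) <= 0) ||
      search_offsets[1] <= 0) {
    abort("`search_offsets` must be strictly increasing and positive.")
  }

  t1 <- search_offsets[1]
  if (arrival == "point") {
    persist <- S(search_offsets)
  } else {
    # P(persist to search m) = (1/t1) * int_0^t1 S(t_m - t1 + u) du for
    # all m at once: composite Simpson on a shared 41-node grid (S is
    # smooth; fixed quadrature keeps the bootstrap hot path cheap).
    nn <- 41L
    u <- seq(0, t1, length.out = nn)
    wq <- c(1, rep(c(4, 2), length.out = nn - 2), 1)
    wq[nn] <- 1
    wq <- wq * (t1 / (nn - 1)) / 3
    tt <- outer(search_offsets - t1, u, `+`)
    persist <- as.vector(matrix(S(tt), nrow = length(search_offsets)) %*%
                           wq) / t1
  }
  g <- 0
  miss <- 1
  for (m in seq_along(search_offsets)) {
    pm <- p * k^(m - 1)
    term <- persist[m] * pm * miss
    g <- g + term
    if (term < tol) break
    miss <- miss * (1 - pm)
  }
  if (g <= 0) {
    abort("Detection probability is zero; the estimator is undefined.",
          class = "curtailr_estimation_error")
  }
  g
}
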