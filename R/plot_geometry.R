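#' Square carcass-search plot geometry
#'
#' Carcass searches are conducted on square plots centred on the turbine
#' base.  A square plot of half-width `a` metres (side length `2a`) fully
#' covers every circle of radius up to `a`, but only the corners of the
#' plot are searched between `a` and the corner distance `a * sqrt(2)`;
#' observed carcass distances are therefore right-truncated at the corner
#' distance.
#'
#' @param half_width Half the side length of the square plot, in metres.
#'   The default 40 corresponds to an 80 m x 80 m plot.
#'
#' @return An object of class `square_plot`: a list with elements
#'   `half_width` and `truncation_distance` (`half_width * sqrt(2)`, the
#'   corner distance), both in metres.
#'
#' @examples
#' plot <- square_plot(40)
#' corner_truncation_distance(plot)  # 56.57 m
#' @export
square_plot <- function(half_width = 40) {
  if (!is.numeric(half_width) || length(half_width) != 1 ||
      !is.finite(half_width) || half_width <= 0) {
    abort("`half_width` must be a single positive number (metres).")
  }
  structure(
    list(half_width = half_width, truncation_distance = half_width * sqrt(2)),
    class = "square_plot"
  )
}

#' @export
print.square_plot <- function(x, ...) {
  cat(sprintf(
    "<square_plot> %g m x %g m (half-width %g m, corner distance %.2f m)\n",
    2 * x$half_width, 2 * x$half_width, x$half_width, x$truncation_distance
  ))
  invisible(x)
}

check_plot <- function(plot) {
  if (!inherits(plot, "square_plot")) {
    abort("`plot` must be a `square_plot` object (see `square_plot()`).")
  }
  plot
}

#' Corner truncation distance of a square plot
#'
#' The largest turbine-to-carcass distance observable on a square plot:
#' the distance from the plot centre to a corner, `half_width * sqrt(2)`.
#'
#' @param plot A [square_plot()].
#' @return Distance in metres.
#' @examples
#' corner_truncation_distance(square_plot(40))
#' @export
corner_truncation_distance <- function(plot) {
  check_plot(plot)$truncation_distance
}

#' Fraction of a circle's circumference inside the square plot
#'
#' For a carcass at distance `d` from the turbine with uniformly random
#' bearing, the probability that it lands inside the square plot is the
#' fraction of the radius-`d` circle lying inside the square: 1 up to the
#' half-width `a`, falling to 0 at the corner distance `a * sqrt(2)`.
#' This is the pointwise inclusion probability `psi(d)` used to weight
#' observations in the truncated weighted likelihood.
#'
#' @param d Distance(s) from the turbine base, metres.  Vectorised.
#' @param plot A [square_plot()].
#' @return Proportion(s) in `[0, 1]`.
#' @examples
#' circle_inclusion_fraction(c(30, 45, 60), square_plot(40))
#' @export
circle_inclusion_fraction <- function(d, plot) {
  check_plot(plot)
  if (any(!is.finite(d) | d < 0)) {
    abort("`d` must be non-negative finite distances.")
  }
  a <- plot$half_width
  tau <- plot$truncation_distance
  out <- numeric(length(d))
  out[d <= a] <- 1
  mid <- d > a & d < tau
  out[mid] <- 1 - (4 / pi) * acos(a / d[mid])
  # d >= tau stays 0
  out
}

# Area of the disc of radius R (centred on the plot centre) that lies
# inside the square of half-width a.  Closed form; vectorised over R.
disc_area_inside <- function(R, plot) {
  a <- plot$half_width
  tau <- plot$truncation_distance
  out <- pi * R^2
  mid <- R > a & R < tau
  Rm <- R[mid]
  out[mid] <- pi * Rm^2 - 4 * (Rm^2 * acos(a / Rm) - a * sqrt(Rm^2 - a^2))
  out[R >= tau] <- 4 * a^2
  out
}

#' Searched-area fraction of an annulus
#'
#' The fraction of the annulus `[d_lo, d_hi)` around the turbine that lies
#' inside the square search plot.  This is the search-effort weight used
#' when integrating a fitted carcass distance density into the area
#' correction: each 1-m annulus's predicted carcass fraction is multiplied
#' by the fraction of that annulus actually searched.
#'
#' @param d_lo,d_hi Inner and outer annulus radii in metres
#'   (`0 <= d_lo < d_hi`).  Vectorised in parallel.
#' @param plot A [square_plot()].
#' @return Proportion(s) in `[0, 1]`.
#' @examples
#' annulus_searched_fraction(40, 41, square_plot(40))
#' @export
annulus_searched_fraction <- function(d_lo, d_hi, plot) {
  check_plot(plot)
  if (any(!is.finite(d_lo) | !is.finite(d_hi) | d_lo < 0 | d_lo >= d_hi)) {
    abort("Annulus bounds must satisfy 0 <= d_lo < d_hi.")
  }
  (disc_area_inside(d_hi, plot) - disc_area_inside(d_lo, plot)) /
    (pi * (d_hi^2 - d_lo^2))
}

#' Annulus decomposition of a square search plot
#'
#' Splits the plot into concentric 1-m (by default) annuli from the
#' turbine base out to the corner distance, with the searched-area
#' fraction of each.  The final annulus is truncated at the corner
#' distance.
#'
#' @param plot A [square_plot()].
#' @param width Annulus width in metres (default 1).
#' @return A tibble with columns `d_lo`, `d_hi`, `area_m2` (full annulus
#'   area) and `searched_fraction`.
#' @examples
#' annulus_table(square_plot(40))
#' @export
annulus_table <- function(plot, width = 1) {
  check_plot(plot)
  tau <- plot$truncation_distance
  edges <- unique(c(seq(0, tau, by = width), tau))
  lo <- edges[-length(edges)]
  hi <- edges[-1]
  tibble::tibble(
    d_lo = lo,
    d_hi = hi,
    area_m2 = pi * (hi^2 - lo^2),
    searched_fraction = annulus_searched_fraction(lo, hi, plot)
  )
}
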