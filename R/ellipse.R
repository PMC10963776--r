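#' Wind-driven ellipse length-to-breadth ratio
#'
#' Anderson's (1983) relation between open windspeed and the elongation of a
#' wind-driven elliptical fire, capped at `lb_max`: the fire is circular in
#' calm air and becomes longer and narrower as windspeed increases.
#'
#' @param windspeed Open windspeed, km/h (>= 0).
#' @param lb_max Upper cap on the length-to-breadth ratio (default 8).
#' @return Length-to-breadth ratio (>= 1), same length as `windspeed`.
#' @export
length_to_breadth <- function(windspeed, lb_max = 8) {
  if (any(windspeed < 0)) stop("`windspeed` must be >= 0", call. = FALSE)
  u <- windspeed / 3.6    # km/h -> m/s
  lb <- 0.936 * exp(0.2566 * u) + 0.461 * exp(-0.1548 * u) - 0.397
  pmin(pmax(lb, 1), lb_max)
}

#' Per-angle elliptical growth factors
#'
#' With the ignition at the rear focus of the ellipse, the radial growth at
#' angle `theta` from the heading direction, relative to the head, is
#' `g(theta) = (1 - e) / (1 - e * cos(theta))` where
#' `e = sqrt(1 - 1 / LB^2)` is the eccentricity. `g(0) = 1` at the head and
#' `g` decreases monotonically to `(1 - e) / (1 + e)` at the back.
#'
#' @param lb Length-to-breadth ratio (>= 1), scalar.
#' @param angles Angle grid in radians, measured from the heading direction
#'   (default 360 uniform bin centers over `[0, 2*pi)`).
#' @return Vector of unitless growth factors in `(0, 1]`.
#' @export
ellipse_factors <- function(lb, angles = angle_grid()) {
  if (length(lb) != 1 || is.na(lb) || lb < 1)
    stop("`lb` must be a single value >= 1", call. = FALSE)
  e <- sqrt(1 - 1 / lb^2)
  (1 - e) / (1 - e * cos(angles))
}

#' Uniform angle grid
#'
#' Bin centers of `n` uniform angular bins over `[0, 2*pi)`, with the heading
#' direction at angle 0.
#'
#' @param n Number of angular bins (default 360).
#' @return Numeric vector of bin-center angles in radians.
#' @export
angle_grid <- function(n = 360) {
  (seq_len(n) - 0.5) * 2 * pi / n
}

#' Area enclosed by a per-angle perimeter
#'
#' Polar integration of the perimeter: `area = sum(r^2 / 2 * dtheta)` over the
#' uniform angle grid, converted from m^2 to hectares. Exact for a circle in
#' the fine-bin limit.
#'
#' @param radial_dist Per-bin radial distances from the ignition point, m.
#' @return Area in hectares.
#' @export
polar_area <- function(radial_dist) {
  if (any(radial_dist < 0)) stop("distances must be >= 0", call. = FALSE)
  dtheta <- 2 * pi / length(radial_dist)
  sum(radial_dist^2) * dtheta / 2 / 1e4
}

#' Fireline intensity around an elliptical perimeter
#'
#' Following Catchpole and colleagues, Byram intensity at a point on the
#' perimeter scales with the local normal spread rate at constant heat per
#' unit area, so `I(theta) = I_head * g(theta)` with `g` from
#' [ellipse_factors()]: maximal at the head, minimal at the back.
#'
#' @param intensity_head Heading fireline intensity, kW/m (>= 0).
#' @param g Per-angle growth factors from [ellipse_factors()].
#' @return Per-angle fireline intensity, kW/m.
#' @export
perimeter_intensity <- function(intensity_head, g) {
  if (any(intensity_head < 0)) stop("`intensity_head` must be >= 0", call. = FALSE)
  intensity_head * g
}
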