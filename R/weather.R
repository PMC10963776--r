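#' Default weather-generator parameters
#'
#' Parameters of the seeded fire-season weather generator: Weibull daily
#' windspeeds with a single per-fire wind direction, and a latent daily vapor
#' pressure deficit (VPD) signal -- seasonal sinusoid plus temporally
#' autocorrelated AR(1) fluctuations -- that drives all fuel-moisture classes.
#'
#' @param wind_shape Weibull shape of daily open windspeed (unitless).
#' @param wind_scale Weibull scale of daily open windspeed (km/h). The default
#'   gives a mean daily windspeed of about 10 km/h.
#' @param vpd_amp Seasonal sinusoid amplitude of daily VPD (kPa); the season
#'   is driest at mid-season.
#' @param vpd_amp_sd Lognormal standard deviation of the per-fire random
#'   amplitude multiplier (unitless).
#' @param ar_phi AR(1) coefficient of daily VPD fluctuations, in [0, 1).
#' @param ar_sd Stationary standard deviation of the AR(1) VPD fluctuations
#'   (kPa).
#' @param peak_day Day of season at which the seasonal sinusoid is driest.
#' @param vpd_floor Lower bound for daily VPD (kPa), keeping moistures finite.
#' @param fm_a,fm_b,fm_c Coefficients of the negative-exponential VPD to dead
#'   fuel moisture map `fm = a * exp(-b * vpd) + c` (moisture as a fraction of
#'   oven-dry weight, VPD in kPa).
#' @param alpha_10h,alpha_100h Exponential-smoothing coefficients lagging and
#'   damping the 1-h aridity signal for the 10-h and 100-h classes.
#' @param offset_10h,offset_100h Additive moisture offsets (fraction) for the
#'   10-h and 100-h classes relative to the 1-h map.
#' @param herb_a,herb_b,herb_floor Live herbaceous moisture map
#'   `max(floor, a * exp(-b * vpd_smooth))`.
#' @param woody_a,woody_b,woody_floor Live woody moisture map, same form.
#' @param canopy_base,canopy_amp Canopy foliar moisture sinusoid: base value
#'   at season edges minus `canopy_amp * sin(pi * day / season)` at mid-season.
#'
#' @return A named list of generator parameters.
#' @export
weather_params <- function(wind_shape = 1.7,
                           wind_scale = 11.28,
                           vpd_amp = 0.55,
                           vpd_amp_sd = 0.25,
                           ar_phi = 0.7,
                           ar_sd = 0.33,
                           peak_day = 75,
                           vpd_floor = 0.05,
                           fm_a = 0.269, fm_b = 0.69, fm_c = 0.035,
                           alpha_10h = 0.5, alpha_100h = 0.12,
                           offset_10h = 0.01, offset_100h = 0.02,
                           herb_a = 2.4, herb_b = 0.5, herb_floor = 0.30,
                           woody_a = 1.8, woody_b = 0.3, woody_floor = 0.60,
                           canopy_base = 1.2, canopy_amp = 0.3) {
  stopifnot(wind_shape > 0, wind_scale > 0,
            ar_phi >= 0, ar_phi < 1, ar_sd >= 0,
            fm_a > 0, fm_b > 0, fm_c >= 0)
  as.list(environment())
}

#' Sample a uniform ignition day from the fire season
#'
#' @param season_length Length of the fire season in days (default 150).
#' @param n Number of ignition days to draw.
#' @return Integer vector in `[1, season_length]`.
#' @export
sample_ignition_day <- function(season_length = 150, n = 1) {
  if (length(season_length) != 1 || is.na(season_length) || season_length < 1)
    stop("`season_length` must be a positive number of days", call. = FALSE)
  sample.int(as.integer(season_length), n, replace = TRUE)
}

#' Simulate daily windspeeds and a single wind direction
#'
#' Daily open windspeeds are independent Weibull draws; one wind direction is
#' drawn uniformly on [0, 360) degrees and held constant for the fire event.
#'
#' @param season_length Days in the fire season.
#' @param shape,scale Weibull shape (unitless) and scale (km/h).
#' @return A list with `windspeed` (km/h, length `season_length`) and
#'   `wind_direction` (degrees).
#' @export
simulate_wind <- function(season_length = 150, shape = 1.7, scale = 11.28) {
  if (shape <= 0 || scale < 0)
    stop("Weibull `shape` must be > 0 and `scale` >= 0", call. = FALSE)
  list(windspeed = stats::rweibull(season_length, shape = shape, scale = scale),
       wind_direction = stats::runif(1, 0, 360))
}

#' Convert vapor pressure deficit to dead fuel moisture
#'
#' Negative-exponential map `fm = a * exp(-b * vpd) + c`: strictly decreasing
#' in VPD, bounded above by `a + c` and below by `c`, and invertible (used by
#' the years-equivalent conversion).
#'
#' @param vpd Vapor pressure deficit, kPa (> 0).
#' @param params Weather parameters from [weather_params()] (fields `fm_a`,
#'   `fm_b`, `fm_c`).
#' @return Dead (1-h) fuel moisture as a fraction of oven-dry weight.
#' @export
vpd_to_dead_fuel_moisture <- function(vpd, params = weather_params()) {
  if (any(!is.finite(vpd)) || any(vpd <= 0))
    stop("`vpd` must be positive and finite", call. = FALSE)
  fm <- params$fm_a * exp(-params$fm_b * vpd) + params$fm_c
  pmin(pmax(fm, 1e-4), 0.35)
}

# Standardized random innovations for one ignition, drawn from the current RNG
# stream. Keeping innovations separate from series construction lets the same
# draws be replayed across every gradient level (common random numbers).
weather_innovations <- function(season_length = 150) {
  list(
    wind_u   = stats::runif(season_length),
    dir_u    = stats::runif(1),
    amp_z    = stats::rnorm(1),
    ar_z     = stats::rnorm(season_length),
    day_u    = stats::runif(1),
    ia_u     = stats::runif(1)
  )
}

#' Simulate one fire season of daily weather
#'
#' Builds a 150-day (by default) series of daily windspeed and fuel moistures
#' anchored to a mean seasonal fuel aridity (`mean_vpd`). The latent daily VPD
#' is a seasonal sinusoid (driest at `peak_day`) with a per-fire random
#' amplitude, plus AR(1) fluctuations; dead-class moistures are the latent VPD
#' mapped through [vpd_to_dead_fuel_moisture()], with the 10-h and 100-h
#' classes lagging and damping the 1-h signal. Live and canopy moistures
#' follow their own monotone maps and sinusoid.
#'
#' @param mean_vpd Mean fire-season vapor pressure deficit, kPa.
#' @param season_length Days in the season (default 150).
#' @param params Generator parameters from [weather_params()].
#' @param innov Optional pre-drawn innovations (internal; enables common
#'   random numbers across gradient levels). When `NULL`, drawn from the
#'   current RNG stream.
#' @return A list of class `fire_weather`: `days` (a tibble with one row per
#'   day: `day`, `windspeed`, `vpd`, `dead_fm_1h`, `dead_fm_10h`,
#'   `dead_fm_100h`, `live_herb_fm`, `live_woody_fm`, `canopy_foliar_fm`),
#'   `wind_direction` (degrees), `ignition_day`, and `mean_vpd`.
#' @export
simulate_weather <- function(mean_vpd, season_length = 150,
                             params = weather_params(), innov = NULL) {
  if (mean_vpd <= 0) stop("`mean_vpd` must be positive", call. = FALSE)
  if (season_length < 1) stop("`season_length` must be >= 1", call. = FALSE)
  if (is.null(innov)) innov <- weather_innovations(season_length)

  t <- seq_len(season_length)
  # seasonal sinusoid, mean-centred so the series stays anchored at mean_vpd
  s <- sin(pi * t / season_length)
  amp <- params$vpd_amp *
    exp(params$vpd_amp_sd * innov$amp_z - params$vpd_amp_sd^2 / 2)
  seasonal <- amp * (s - mean(s))

  # AR(1) fluctuations with stationary sd ar_sd
  phi <- params$ar_phi
  innov_sd <- params$ar_sd * sqrt(1 - phi^2)
  eps <- as.numeric(stats::filter(innov$ar_z * innov_sd, phi,
                                  method = "recursive",
                                  init = innov$ar_z[1] * params$ar_sd))

  vpd <- pmax(mean_vpd + seasonal + eps, params$vpd_floor)

  smooth1 <- function(x, alpha) {
    as.numeric(stats::filter(alpha * x, 1 - alpha, method = "recursive",
                             init = mean_vpd))
  }
  vpd10 <- pmax(smooth1(vpd, params$alpha_10h), params$vpd_floor)
  vpd100 <- pmax(smooth1(vpd, params$alpha_100h), params$vpd_floor)

  fm1 <- vpd_to_dead_fuel_moisture(vpd, params)
  fm10 <- pmin(vpd_to_dead_fuel_moisture(vpd10, params) + params$offset_10h, 0.35)
  fm100 <- pmin(vpd_to_dead_fuel_moisture(vpd100, params) + params$offset_100h, 0.35)

  herb <- pmax(params$herb_floor, params$herb_a * exp(-params$herb_b * vpd100))
  woody <- pmax(params$woody_floor, params$woody_a * exp(-params$woody_b * vpd100))
  canopy <- pmax(0.6, params$canopy_base - params$canopy_amp * s)

  wind <- stats::qweibull(innov$wind_u, shape = params$wind_shape,
                          scale = params$wind_scale)

  structure(list(
    days = tibble::tibble(
      day = t,
      windspeed = wind,
      vpd = vpd,
      dead_fm_1h = fm1,
      dead_fm_10h = fm10,
      dead_fm_100h = fm100,
      live_herb_fm = herb,
      live_woody_fm = woody,
      canopy_foliar_fm = canopy
    ),
    wind_direction = 360 * innov$dir_u,
    ignition_day = max(1L, ceiling(innov$day_u * season_length)),
    mean_vpd = mean_vpd,
    ia_u = innov$ia_u
  ), class = "fire_weather")
}

#' @export
print.fire_weather <- function(x, ...) {
  cat(sprintf(
    "<fire_weather> %d-day season, mean VPD %.2f kPa, ignition day %d, wind dir %.0f deg\n",
    nrow(x$days), x$mean_vpd, x$ignition_day, x$wind_direction))
  print(x$days, n = 5)
  invisible(x)
}
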