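#' Simulation parameters
#'
#' Numerical and procedural knobs of the per-fire simulation.
#'
#' @param n_angles Angular bins on the perimeter grid (default 360).
#' @param active_hours Hours of active spread per day; daily spread distance
#'   is `ros * active_hours * 60` at the head. The default 7.5 h is half of a
#'   15-hour mid-summer day.
#' @param extinguish_m Per-angle permanent-extinction rule: a perimeter point
#'   burning less than this distance (m) in a day is permanently extinguished
#'   (default 5).
#' @param smolder_days Days an ignition may smolder waiting for fuel moisture
#'   to drop below the moisture of extinction (default 3).
#' @param ia_coef Coefficients of [initial_attack_probability()].
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_angles = 360, active_hours = 7.5, extinguish_m = 5,
                       smolder_days = 3,
                       ia_coef = c(b0 = 25.2, b_intensity = 3.1, b_size = 1.5)) {
  stopifnot(n_angles >= 8, active_hours > 0, extinguish_m >= 0,
            smolder_days >= 1)
  structure(list(n_angles = as.integer(n_angles), active_hours = active_hours,
                 extinguish_m = extinguish_m,
                 smolder_days = as.integer(smolder_days), ia_coef = ia_coef),
            class = "sim_params")
}

# Internal fast path: returns a plain list (one fire record), optionally with
# per-day ring detail. `behavior` may be precomputed once per weather/fuel
# combination and shared across all scenarios.
sim_fire_record <- function(weather, fuels, scenario, mapping, sim,
                            behavior = NULL, u_ia = NULL,
                            keep_rings = FALSE) {
  if (is.null(behavior)) behavior <- fire_behavior(fuels, weather)
  if (is.null(u_ia)) u_ia <- if (!is.null(weather$ia_u)) weather$ia_u else stats::runif(1)
  season_length <- nrow(weather$days)
  d0 <- weather$ignition_day
  mx <- fuels$moisture_of_extinction

  rec <- list(ignition_day = d0, spread_day = NA_integer_,
              smoldered = TRUE, contained_ia = FALSE,
              final_area = 0, duration = 0L,
              prop_high_severity = NA_real_, mean_cbi = NA_real_,
              cbi_mad = NA_real_, n_crown_days = 0L, rings = NULL)

  # smoldering: spread begins on the first of up to `smolder_days` days with
  # fine dead fuel moisture below the moisture of extinction
  window <- d0:min(d0 + sim$smolder_days - 1L, season_length)
  ok <- window[weather$days$dead_fm_1h[window] < mx & behavior$ros[window] > 0]
  if (length(ok) == 0) return(rec)
  start <- ok[1]
  rec$spread_day <- start
  rec$smoldered <- FALSE

  theta <- angle_grid(sim$n_angles)
  cos_t <- cos(theta)
  dtheta <- 2 * pi / sim$n_angles
  thr <- mapping$high_severity_threshold

  # initial attack (regressive scenarios only)
  if (!is.na(scenario$engagement_delay)) {
    ia <- attempt_initial_attack(behavior$ros[start], behavior$intensity[start],
                                 behavior$lb[start], scenario, u = u_ia,
                                 ia_coef = sim$ia_coef,
                                 n_angles = sim$n_angles)
    if (ia$contained) {
      e <- behavior$ecc[start]
      g <- (1 - e) / (1 - e * cos_t)
      r <- behavior$ros[start] * scenario$engagement_delay * 60 * g
      w <- r^2 * dtheta / 2 / 1e4
      cbi <- flame_length_to_cbi(
        byram_flame_length(behavior$intensity[start] * g), mapping)
      m <- severity_metrics(w, cbi, thr)
      rec$contained_ia <- TRUE
      rec$final_area <- ia$size_ha
      rec$duration <- 1L
      rec$prop_high_severity <- m$prop_high_severity
      rec$mean_cbi <- m$mean_cbi
      rec$cbi_mad <- m$cbi_mad
      if (keep_rings)
        rec$rings <- tibble::tibble(day = start, angle = theta, dist = r,
                                    area = w, intensity = behavior$intensity[start] * g,
                                    cbi = cbi)
      return(rec)
    }
  }

  r <- numeric(sim$n_angles)
  active <- rep(TRUE, sim$n_angles)
  minutes <- sim$active_hours * 60
  max_days <- season_length - start + 1L
  area_acc <- vector("list", max_days)
  cbi_acc <- vector("list", max_days)
  rings <- if (keep_rings) vector("list", max_days) else NULL
  n_crown <- 0L
  last_day <- start - 1L

  for (day in start:season_length) {
    ros_d <- behavior$ros[day]
    k <- day - start + 1L
    if (ros_d <= 0) break   # no spread anywhere: every point burns < 5 m
    e <- behavior$ecc[day]
    g <- (1 - e) / (1 - e * cos_t)
    local_i <- behavior$intensity[day] * g

    inc <- numeric(sim$n_angles)
    inc[active] <- ros_d * minutes * g[active] *
      (1 - containment_fraction(local_i[active], scenario))

    burned <- active & inc > 0
    if (any(burned)) {
      r_new <- r
      r_new[burned] <- r[burned] + inc[burned]
      w <- (r_new[burned]^2 - r[burned]^2) * dtheta / 2 / 1e4
      cbi <- flame_length_to_cbi(byram_flame_length(local_i[burned]), mapping)
      area_acc[[k]] <- w
      cbi_acc[[k]] <- cbi
      if (keep_rings)
        rings[[k]] <- tibble::tibble(day = day, angle = theta[burned],
                                     dist = r_new[burned], area = w,
                                     intensity = local_i[burned], cbi = cbi)
      r <- r_new
      if (behavior$fire_type[day] != "surface") n_crown <- n_crown + 1L
      last_day <- day
    }

    # permanent extinction of points burning less than the daily threshold
    active <- active & inc >= sim$extinguish_m
    if (!any(active)) break
  }

  areas <- unlist(area_acc, use.names = FALSE)
  cbis <- unlist(cbi_acc, use.names = FALSE)
  rec$final_area <- polar_area(r)
  rec$duration <- max(last_day - start + 1L, 0L)
  rec$n_crown_days <- n_crown
  if (length(areas) > 0 && sum(areas) > 0) {
    m <- severity_metrics(areas, cbis, thr)
    rec$prop_high_severity <- m$prop_high_severity
    rec$mean_cbi <- m$mean_cbi
    rec$cbi_mad <- m$cbi_mad
  }
  if (keep_rings) rec$rings <- dplyr::bind_rows(rings)
  rec
}

#' Simulate one fire from ignition to extinction
#'
#' Runs the full per-fire chain for a given suppression scenario: smoldering
#' (up to three days waiting for fuel moisture below the moisture of
#' extinction, else natural extinction), stochastic initial attack at the
#' scenario's engagement delay, then the daily loop of fire behavior,
#' elliptical growth at every perimeter angle for half the day length,
#' intensity-dependent suppression of each angle's spread, ring severity, and
#' per-angle permanent extinction when daily spread falls below 5 m. The fire
#' ends when every angle is extinguished or the 150-day season ends.
#'
#' @param weather A `fire_weather` from [simulate_weather()].
#' @param fuels A [fuel_complex()].
#' @param scenario A [suppression_scenario()].
#' @param mapping A [severity_mapping()].
#' @param sim A [sim_params()].
#' @param behavior Optional precomputed [fire_behavior()] table for this
#'   weather/fuel combination (shared across scenarios).
#' @param u_ia Optional uniform draw for initial attack (defaults to the
#'   draw carried by `weather`, keeping scenario contrasts paired).
#' @param keep_rings If `TRUE`, attach the per-day per-angle ring table.
#' @return A one-row tibble (the fire record): `ignition_day`, `spread_day`,
#'   `smoldered`, `contained_ia`, `final_area` (ha), `duration` (days),
#'   `prop_high_severity`, `mean_cbi`, `cbi_mad`, `n_crown_days`, `scenario`.
#'   With `keep_rings = TRUE` the ring table is attached as attribute
#'   `"rings"`.
#' @export
simulate_fire <- function(weather, fuels, scenario, mapping = severity_mapping(),
                          sim = sim_params(), behavior = NULL, u_ia = NULL,
                          keep_rings = FALSE) {
  rec <- sim_fire_record(weather, fuels, scenario, mapping, sim,
                         behavior = behavior, u_ia = u_ia,
                         keep_rings = keep_rings)
  out <- tibble::tibble(
    ignition_day = rec$ignition_day, spread_day = rec$spread_day,
    smoldered = rec$smoldered, contained_ia = rec$contained_ia,
    final_area = rec$final_area, duration = rec$duration,
    prop_high_severity = rec$prop_high_severity, mean_cbi = rec$mean_cbi,
    cbi_mad = rec$cbi_mad, n_crown_days = rec$n_crown_days,
    scenario = scenario$name)
  if (keep_rings) attr(out, "rings") <- rec$rings
  out
}

#' Area-weighted severity metrics of one fire
#'
#' Computes the proportion of burned area at high severity, the
#' area-weighted mean CBI, and the area-weighted mean absolute deviation of
#' CBI (the diversity-of-fire-effects metric) over a fire's ring increments.
#'
#' @param areas Ring area increments, ha (>= 0, summing to the fire's area).
#' @param cbi Ring CBI values in [0, 3].
#' @param threshold High-severity CBI threshold (default 2.25).
#' @return List with `prop_high_severity`, `mean_cbi`, `cbi_mad`.
#' @export
severity_metrics <- function(areas, cbi, threshold = 2.25) {
  tot <- sum(areas)
  if (length(areas) == 0 || tot <= 0)
    stop("severity metrics require positive burned area", call. = FALSE)
  w <- areas / tot
  mu <- sum(w * cbi)
  list(prop_high_severity = sum(w * (cbi >= threshold)),
       mean_cbi = mu,
       cbi_mad = sum(w * abs(cbi - mu)))
}
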