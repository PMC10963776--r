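# Unit conversions used by the behavior core. All user-facing quantities are
# metric (Mg/ha, cm, kJ/kg, km/h, m/min, kW/m); the steady-state spread system
# is evaluated in its original US units and converted back.
MGHA_TO_LBFT2 <- 1 / 48.8243       # Mg/ha -> lb/ft^2
PERCM_TO_PERFT <- 30.48            # 1/cm -> 1/ft
CM_TO_FT <- 1 / 30.48
KJKG_TO_BTULB <- 1 / 2.326
KMH_TO_FTMIN <- 54.6807
FTMIN_TO_MMIN <- 0.3048
BTUFT2_TO_KJM2 <- 11.3565

# SAV ratios (1/ft) for the coarser classes; the 1-h SAV comes from the fuel
# complex. Live herb/woody use the conventional 1500 1/ft.
SAV_10H <- 109
SAV_100H <- 30
SAV_LIVE <- 1500

#' Rothermel surface fire spread
#'
#' Steady-state surface spread for a multi-class dead/live fuel bed
#' (Rothermel's spread model with Albini's weighting), with the standard wind
#' and slope factors and the dynamic live-fuel moisture of extinction.
#' Vectorized over days: moisture and wind inputs may be equal-length vectors.
#' Spread is forced to zero whenever the 1-h dead fuel moisture reaches the
#' moisture of extinction.
#'
#' @param fuels A [fuel_complex()].
#' @param m1,m10,m100 Dead fuel moistures (fraction of oven-dry weight).
#' @param mherb,mwoody Live fuel moistures (fraction).
#' @param wind Open windspeed, km/h (converted to midflame via
#'   `fuels$wind_adj`).
#' @return A tibble with one row per input day: `ros` (m/min), `intensity`
#'   (Byram fireline intensity, kW/m), `flame_length` (m), `hpua` (heat per
#'   unit area, kJ/m^2), and `reaction_intensity` (kW/m^2).
#' @export
surface_spread <- function(fuels, m1, m10, m100, mherb, mwoody, wind) {
  n <- max(length(m1), length(wind))
  m1 <- rep_len(m1, n); m10 <- rep_len(m10, n); m100 <- rep_len(m100, n)
  mherb <- rep_len(mherb, n); mwoody <- rep_len(mwoody, n)
  wind <- rep_len(wind, n)

  w0 <- c(fuels$load_1h, fuels$load_10h, fuels$load_100h,
          fuels$load_live_herb, fuels$load_live_woody) * MGHA_TO_LBFT2
  sav <- c(fuels$sav_1h * PERCM_TO_PERFT, SAV_10H, SAV_100H, SAV_LIVE, SAV_LIVE)
  h <- rep(fuels$heat_content * KJKG_TO_BTULB, 5)
  delta <- fuels$fuelbed_depth * CM_TO_FT
  mx_dead <- fuels$moisture_of_extinction
  dead <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  st <- 0.0555; se <- 0.010; rho_p <- 32

  if (sum(w0[dead]) <= 0 || delta <= 0) {
    zero <- rep(0, n)
    return(tibble::tibble(ros = zero, intensity = zero, flame_length = zero,
                          hpua = zero, reaction_intensity = zero))
  }

  # surface-area weighting within and across categories
  a <- sav * w0
  a_dead <- sum(a[dead]); a_live <- sum(a[!dead])
  f <- ifelse(dead, a / max(a_dead, 1e-12), a / max(a_live, 1e-12))
  f_dead <- a_dead / (a_dead + a_live)
  f_live <- 1 - f_dead
  sav_dead <- sum(f[dead] * sav[dead])
  sav_live <- if (a_live > 0) sum(f[!dead] * sav[!dead]) else 0
  sav_c <- f_dead * sav_dead + f_live * sav_live

  rho_b <- sum(w0) / delta
  beta <- rho_b / rho_p
  beta_op <- 3.348 * sav_c^-0.8189
  rel_pack <- beta / beta_op

  gamma_max <- sav_c^1.5 / (495 + 0.0594 * sav_c^1.5)
  a_exp <- 133 * sav_c^-0.7913
  gamma <- gamma_max * rel_pack^a_exp * exp(a_exp * (1 - rel_pack))

  wn <- w0 * (1 - st)
  wn_dead <- sum(f[dead] * wn[dead])
  wn_live <- sum(f[!dead] * wn[!dead])

  # per-day category moistures
  m <- rbind(m1, m10, m100, mherb, mwoody)   # 5 x n
  m_dead <- colSums(f[dead] * m[dead, , drop = FALSE])
  m_live <- if (a_live > 0) colSums(f[!dead] * m[!dead, , drop = FALSE]) else rep(0, n)

  # dynamic live moisture of extinction
  eps138 <- exp(-138 / sav)
  if (a_live > 0) {
    w_rat <- sum(w0[dead] * eps138[dead]) /
      max(sum(w0[!dead] * exp(-500 / sav[!dead])), 1e-12)
    mfd <- colSums(w0[dead] * eps138[dead] * m[dead, , drop = FALSE]) /
      sum(w0[dead] * eps138[dead])
    mx_live <- pmax(2.9 * w_rat * (1 - mfd / mx_dead) - 0.226, mx_dead)
  } else {
    mx_live <- rep(mx_dead, n)
  }

  damp <- function(mc, mx) {
    r <- pmin(mc / mx, 1)
    eta <- 1 - 2.59 * r + 5.11 * r^2 - 3.52 * r^3
    ifelse(mc >= mx, 0, pmax(eta, 0))
  }
  eta_m_dead <- damp(m_dead, mx_dead)
  eta_m_live <- if (a_live > 0) damp(m_live, mx_live) else rep(0, n)
  eta_s <- 0.174 * se^-0.19

  ir <- gamma * (wn_dead * h[1] * eta_m_dead + wn_live * h[1] * eta_m_live) * eta_s

  xi <- exp((0.792 + 0.681 * sqrt(sav_c)) * (beta + 0.1)) /
    (192 + 0.2595 * sav_c)

  qig <- 250 + 1116 * m
  sink_dead <- colSums(f[dead] * eps138[dead] * qig[dead, , drop = FALSE])
  sink_live <- if (a_live > 0)
    colSums(f[!dead] * eps138[!dead] * qig[!dead, , drop = FALSE]) else rep(0, n)
  sink <- rho_b * (f_dead * sink_dead + f_live * sink_live)

  r0 <- ir * xi / pmax(sink, 1e-12)

  u <- wind * fuels$wind_adj * KMH_TO_FTMIN
  u <- pmin(u, 0.9 * ir)   # Rothermel's effective-wind limit
  cc <- 7.47 * exp(-0.133 * sav_c^0.55)
  bb <- 0.02526 * sav_c^0.54
  ee <- 0.715 * exp(-3.59e-4 * sav_c)
  phi_w <- cc * u^bb * rel_pack^-ee
  phi_s <- 5.275 * beta^-0.3 * (fuels$slope / 100)^2

  ros_ft <- r0 * (1 + phi_w + phi_s)

  # extinction: no spread once fine dead fuels reach the moisture of extinction
  out <- m1 >= mx_dead | m_dead >= mx_dead
  ros_ft[out] <- 0

  t_r <- 384 / sav_c                       # residence time, min
  hpua <- ir * t_r * BTUFT2_TO_KJM2        # kJ/m^2
  ros <- ros_ft * FTMIN_TO_MMIN
  intensity <- hpua * ros / 60             # kW/m
  intensity[out] <- 0
  rint <- ir * BTUFT2_TO_KJM2 / 60         # kW/m^2

  tibble::tibble(ros = ros, intensity = intensity,
                 flame_length = byram_flame_length(intensity),
                 hpua = hpua, reaction_intensity = rint)
}

#' Crown fire transition and final fire behavior
#'
#' Applies the Van Wagner crown-ignition criterion to a surface fire state:
#' crowning begins when surface fireline intensity reaches the critical value
#' `I0 = (0.01 * CBH * (460 + 25.9 * FMC%))^1.5` (CBH in m). Crown spread rate
#' uses a Cruz-style wind/fuel-driven form; the fire is an active crown fire
#' when the crown rate reaches the critical mass-flow rate `3 / CBD`, and a
#' passive crown fire otherwise (crown fraction burned scales the canopy fuel
#' consumed). Vectorized over days.
#'
#' @param surface A tibble from [surface_spread()].
#' @param fuels A [fuel_complex()].
#' @param wind Open windspeed, km/h.
#' @param m1 1-h dead fuel moisture (fraction).
#' @param canopy_fm Canopy foliar moisture (fraction).
#' @return A tibble: `ros` (m/min, final heading rate), `intensity` (kW/m,
#'   including canopy fuel consumed), `flame_length` (m), `fire_type`
#'   (`"surface"`, `"passive_crown"`, `"active_crown"`), `hpua` (kJ/m^2).
#' @export
crown_transition <- function(surface, fuels, wind, m1, canopy_fm) {
  n <- nrow(surface)
  wind <- rep_len(wind, n); m1 <- rep_len(m1, n)
  canopy_fm <- rep_len(canopy_fm, n)
  cbh <- fuels$canopy_base_height
  cbd <- fuels$canopy_bulk_density
  cfl_kgm2 <- fuels$canopy_fuel_load / 10   # Mg/ha -> kg/m^2

  if (is.null(cbh) || is.null(cbd) || cbd <= 0 || cfl_kgm2 <= 0 || cbh <= 0) {
    return(tibble::tibble(ros = surface$ros, intensity = surface$intensity,
                          flame_length = surface$flame_length,
                          fire_type = rep("surface", n), hpua = surface$hpua))
  }

  i0 <- (0.01 * cbh * (460 + 25.9 * canopy_fm * 100))^1.5
  crowning <- surface$intensity >= i0 & surface$ros > 0

  # Cruz et al. active crown spread rate (10-m open wind km/h, CBD kg/m^3,
  # estimated fine fuel moisture %)
  cros <- 11.02 * pmax(wind, 0.1)^0.90 * cbd^0.19 * exp(-0.17 * m1 * 100)
  rac <- 3.0 / cbd
  cfb <- pmin(cros / rac, 1)
  active <- crowning & cfb >= 1

  ros <- surface$ros
  ros[active] <- pmax(cros[active], surface$ros[active])

  hpua <- surface$hpua + ifelse(crowning, cfb, 0) * cfl_kgm2 * fuels$heat_content
  intensity <- hpua * ros / 60
  intensity[surface$ros == 0] <- 0

  tibble::tibble(
    ros = ros,
    intensity = intensity,
    flame_length = byram_flame_length(intensity),
    fire_type = ifelse(!crowning, "surface",
                       ifelse(active, "active_crown", "passive_crown")),
    hpua = hpua
  )
}

#' Daily fire behavior for a weather series
#'
#' Convenience wrapper chaining [surface_spread()] and [crown_transition()]
#' over every day of a simulated weather series.
#'
#' @param fuels A [fuel_complex()].
#' @param weather A `fire_weather` object from [simulate_weather()].
#' @return A tibble with one row per season day: `day`, `ros`, `intensity`,
#'   `flame_length`, `fire_type`, `hpua`, `windspeed`, `lb` (ellipse
#'   length-to-breadth ratio), `ecc` (eccentricity).
#' @export
fire_behavior <- function(fuels, weather) {
  d <- weather$days
  surf <- surface_spread(fuels, d$dead_fm_1h, d$dead_fm_10h, d$dead_fm_100h,
                         d$live_herb_fm, d$live_woody_fm, d$windspeed)
  fin <- crown_transition(surf, fuels, d$windspeed, d$dead_fm_1h,
                          d$canopy_foliar_fm)
  lb <- length_to_breadth(d$windspeed)
  tibble::tibble(day = d$day, ros = fin$ros, intensity = fin$intensity,
                 flame_length = fin$flame_length, fire_type = fin$fire_type,
                 hpua = fin$hpua, windspeed = d$windspeed,
                 lb = lb, ecc = sqrt(1 - 1 / lb^2))
}

#' Byram flame length
#'
#' `FL = 0.0775 * I^0.46` with fireline intensity `I` in kW/m and flame length
#' in m.
#'
#' @param intensity Fireline intensity, kW/m (>= 0).
#' @return Flame length, m.
#' @export
byram_flame_length <- function(intensity) {
  if (any(intensity < 0, na.rm = TRUE))
    stop("`intensity` must be >= 0", call. = FALSE)
  0.0775 * intensity^0.46
}
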