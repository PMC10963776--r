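# Synthetic weather built directly (no RNG): every field constant unless a
# vector is supplied. Used for closed-form geometry oracles and control cases.
make_weather <- function(season_length = 10, windspeed = 10, fm1 = 0.08,
                         fm10 = 0.09, fm100 = 0.10, herb = 1.0, woody = 1.0,
                         canopy = 1.0, ignition_day = 1, mean_vpd = 1.17,
                         ia_u = 0.5) {
  structure(list(
    days = tibble::tibble(
      day = seq_len(season_length),
      windspeed = rep_len(windspeed, season_length),
      vpd = rep_len(mean_vpd, season_length),
      dead_fm_1h = rep_len(fm1, season_length),
      dead_fm_10h = rep_len(fm10, season_length),
      dead_fm_100h = rep_len(fm100, season_length),
      live_herb_fm = rep_len(herb, season_length),
      live_woody_fm = rep_len(woody, season_length),
      canopy_foliar_fm = rep_len(canopy, season_length)
    ),
    wind_direction = 0, ignition_day = as.integer(ignition_day),
    mean_vpd = mean_vpd, ia_u = ia_u
  ), class = "fire_weather")
}

# Surface-only fuel complex (no canopy), for tests that must not crown.
surface_fuels <- function(...) {
  fuel_complex(canopy_bulk_density = 0, canopy_fuel_load = 0, ...)
}

# Cached small runs shared across acceptance tests (built once per session).
.run_cache <- new.env(parent = emptyenv())

baseline_records <- function() {
  if (is.null(.run_cache$baseline)) {
    cfg <- experiment_config(axis = "vpd", n_levels = 1, span_years = 0,
                             n_ignitions = 400, n_replicates = 1, seed = 11)
    .run_cache$baseline <- run_experiment(cfg)
  }
  .run_cache$baseline
}

gradient_records <- function() {
  if (is.null(.run_cache$gradient)) {
    cfg <- experiment_config(axis = "vpd", n_levels = 25, n_ignitions = 200,
                             n_replicates = 1,
                             scenarios = default_scenarios()[c("none", "maximum")],
                             seed = 12)
    .run_cache$gradient <- run_experiment(cfg)
  }
  .run_cache$gradient
}

# Equation-by-equation hand calculation of the steady-state surface spread
# system for a 5-class dead/live fuel bed, written out linearly and kept
# independent of the package implementation.
rothermel_by_hand <- function(fuels, m1, m10, m100, mherb, mwoody, wind_kmh) {
  w0 <- c(fuels$load_1h, fuels$load_10h, fuels$load_100h,
          fuels$load_live_herb, fuels$load_live_woody) / 48.8243
  sav <- c(fuels$sav_1h * 30.48, 109, 30, 1500, 1500)
  h <- fuels$heat_content / 2.326
  delta <- fuels$fuelbed_depth / 30.48
  mx <- fuels$moisture_of_extinction
  m <- c(m1, m10, m100, mherb, mwoody)
  dead <- c(TRUE, TRUE, TRUE, FALSE, FALSE)

  a <- sav * w0
  f <- ifelse(dead, a / sum(a[dead]), a / sum(a[!dead]))
  f_dead <- sum(a[dead]) / sum(a)
  sav_c <- f_dead * sum(f[dead] * sav[dead]) +
    (1 - f_dead) * sum(f[!dead] * sav[!dead])

  rho_b <- sum(w0) / delta
  beta <- rho_b / 32
  beta_op <- 3.348 * sav_c^-0.8189
  g_max <- sav_c^1.5 / (495 + 0.0594 * sav_c^1.5)
  aa <- 133 * sav_c^-0.7913
  gam <- g_max * (beta / beta_op)^aa * exp(aa * (1 - beta / beta_op))

  m_dead <- sum(f[dead] * m[dead])
  m_live <- sum(f[!dead] * m[!dead])
  wr <- sum(w0[dead] * exp(-138 / sav[dead])) /
    sum(w0[!dead] * exp(-500 / sav[!dead]))
  mfd <- sum(w0[dead] * exp(-138 / sav[dead]) * m[dead]) /
    sum(w0[dead] * exp(-138 / sav[dead]))
  mx_live <- max(2.9 * wr * (1 - mfd / mx) - 0.226, mx)
  eta <- function(mc, mxc) {
    r <- min(mc / mxc, 1)
    if (mc >= mxc) 0 else max(1 - 2.59 * r + 5.11 * r^2 - 3.52 * r^3, 0)
  }
  ir <- gam * 0.174 * 0.01^-0.19 * (1 - 0.0555) *
    (sum(f[dead] * w0[dead]) * h * eta(m_dead, mx) +
       sum(f[!dead] * w0[!dead]) * h * eta(m_live, mx_live))

  xi <- exp((0.792 + 0.681 * sqrt(sav_c)) * (beta + 0.1)) /
    (192 + 0.2595 * sav_c)
  sink <- rho_b * (f_dead * sum(f[dead] * exp(-138 / sav[dead]) *
                                  (250 + 1116 * m[dead])) +
                     (1 - f_dead) * sum(f[!dead] * exp(-138 / sav[!dead]) *
                                          (250 + 1116 * m[!dead])))
  r0 <- ir * xi / sink

  u <- min(wind_kmh * fuels$wind_adj * 54.6807, 0.9 * ir)
  phi_w <- 7.47 * exp(-0.133 * sav_c^0.55) * u^(0.02526 * sav_c^0.54) *
    (beta / beta_op)^-(0.715 * exp(-3.59e-4 * sav_c))
  phi_s <- 5.275 * beta^-0.3 * (fuels$slope / 100)^2

  ros <- r0 * (1 + phi_w + phi_s) * 0.3048          # m/min
  hpua <- ir * (384 / sav_c) * 11.3565              # kJ/m^2
  list(ros = ros, intensity = hpua * ros / 60, hpua = hpua)
}


# Area-weighted mean that ignores zero-area (severity-free) fires.
weighted_mean_or_na <- function(x, w) {
  keep <- !is.na(x) & w > 0
  if (!any(keep)) return(NA_real_)
  sum(x[keep] * w[keep]) / sum(w[keep])
}
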