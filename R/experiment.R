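#' Configure the factorial suppression experiment
#'
#' Describes one gradient experiment: ignitions x gradient levels x
#' suppression scenarios x replicates, with common random numbers. The
#' gradient varies either mean fuel aridity (VPD) or 100-h fuel loading while
#' holding the other axis at its baseline (VPD 1.17 kPa; 100-h load
#' 11.23 Mg/ha). Levels span `span_years` years of change at the stated
#' yearly rates (0.00837 kPa/yr; 0.036 Mg/ha/yr).
#'
#' @param axis `"vpd"` (fuel-aridity gradient) or `"fuel_load"`.
#' @param n_levels Gradient levels (default 25).
#' @param n_ignitions Ignitions per replicate (default 1000).
#' @param n_replicates Simulation replicates (default 40; scale down for desk
#'   runs).
#' @param scenarios Named list of [suppression_scenario()]s (default the five
#'   study scenarios).
#' @param span_years Years of change spanned by the gradient (default 240).
#' @param baseline_vpd Baseline mean fire-season VPD, kPa (default 1.17).
#' @param baseline_load Baseline 100-h fuel load, Mg/ha (default 11.23).
#' @param vpd_rate Yearly VPD increase, kPa/yr (default 0.00837).
#' @param load_rate Yearly 100-h fuel-load increase, Mg/ha/yr
#'   (default 0.036).
#' @param season_length Fire-season length, days (default 150).
#' @param weather [weather_params()].
#' @param fuels Baseline [fuel_complex()].
#' @param mapping [severity_mapping()].
#' @param sim [sim_params()].
#' @param seed Master seed; every random stream in the experiment derives
#'   from it.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(axis = c("vpd", "fuel_load"),
                              n_levels = 25, n_ignitions = 1000,
                              n_replicates = 40,
                              scenarios = default_scenarios(),
                              span_years = 240,
                              baseline_vpd = 1.17, baseline_load = 11.23,
                              vpd_rate = 0.00837, load_rate = 0.036,
                              season_length = 150,
                              weather = weather_params(),
                              fuels = fuel_complex(),
                              mapping = severity_mapping(),
                              sim = sim_params(),
                              seed = 1L) {
  axis <- match.arg(axis)
  stopifnot(n_levels >= 1, n_ignitions >= 1, n_replicates >= 1,
            length(scenarios) >= 1, season_length >= 1)
  years <- seq(0, span_years, length.out = n_levels)
  values <- if (axis == "vpd") baseline_vpd + years * vpd_rate
            else baseline_load + years * load_rate
  structure(list(axis = axis, n_levels = n_levels, n_ignitions = n_ignitions,
                 n_replicates = n_replicates, scenarios = scenarios,
                 span_years = span_years, baseline_vpd = baseline_vpd,
                 baseline_load = baseline_load, vpd_rate = vpd_rate,
                 load_rate = load_rate, season_length = season_length,
                 weather = weather, fuels = fuels, mapping = mapping,
                 sim = sim, seed = as.integer(seed),
                 level_years = years, level_values = values),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf(
    paste0("<experiment_config> axis %s: %d levels x %d ignitions x ",
           "%d scenarios x %d replicates = %d fire records\n"),
    x$axis, x$n_levels, x$n_ignitions, length(x$scenarios), x$n_replicates,
    x$n_levels * x$n_ignitions * length(x$scenarios) * x$n_replicates))
  invisible(x)
}

#' Run the factorial suppression experiment
#'
#' Simulates every fire in the factorial design with common random numbers:
#' each ignition's weather innovations, ignition day, and initial-attack draw
#' are reused across all gradient levels and all suppression scenarios, so
#' scenario contrasts are paired -- thousands of fires with identical
#' biophysical conditions that differ only in their suppression scenario.
#' Deterministic given the config's master seed.
#'
#' @param config An [experiment_config()].
#' @param progress Print per-replicate progress messages.
#' @return A tibble with one row per (replicate, ignition, level, scenario):
#'   the fire-record columns of [simulate_fire()] plus `replicate`,
#'   `ignition`, `level` (index), `level_value` (kPa or Mg/ha), and
#'   `level_years` (year-equivalents from the gradient baseline).
#' @export
run_experiment <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  n_scen <- length(config$scenarios)
  n_total <- config$n_replicates * config$n_ignitions * config$n_levels * n_scen
  if (progress)
    message(sprintf("simulating %d fire records (%d replicates x %d ignitions x %d levels x %d scenarios)",
                    n_total, config$n_replicates, config$n_ignitions,
                    config$n_levels, n_scen))

  # per-level inputs: VPD gradient varies weather; fuel-load gradient varies
  # the (ratio-preserving) fuel complex
  fuels_by_level <- lapply(seq_len(config$n_levels), function(l) {
    if (config$axis == "fuel_load")
      scale_fuel_complex(config$fuels, config$level_values[l])
    else scale_fuel_complex(config$fuels, config$baseline_load)
  })
  vpd_by_level <- if (config$axis == "vpd") config$level_values
                  else rep(config$baseline_vpd, config$n_levels)

  set.seed(config$seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1,
                             config$n_replicates * config$n_ignitions),
                  nrow = config$n_replicates)

  cols <- c("ignition_day", "spread_day", "final_area", "duration",
            "prop_high_severity", "mean_cbi", "cbi_mad", "n_crown_days")
  num <- matrix(NA_real_, nrow = n_total, ncol = length(cols),
                dimnames = list(NULL, cols))
  smoldered <- logical(n_total); contained <- logical(n_total)
  scen_idx <- integer(n_total); rep_idx <- integer(n_total)
  ign_idx <- integer(n_total); lvl_idx <- integer(n_total)
  scen_names <- vapply(config$scenarios, `[[`, "", "name")

  row <- 0L
  for (rep_i in seq_len(config$n_replicates)) {
    for (ign in seq_len(config$n_ignitions)) {
      set.seed(seeds[rep_i, ign])
      innov <- weather_innovations(config$season_length)
      for (lvl in seq_len(config$n_levels)) {
        wx <- simulate_weather(vpd_by_level[lvl], config$season_length,
                               config$weather, innov = innov)
        beh <- fire_behavior(fuels_by_level[[lvl]], wx)
        for (s in seq_len(n_scen)) {
          rec <- sim_fire_record(wx, fuels_by_level[[lvl]],
                                 config$scenarios[[s]], config$mapping,
                                 config$sim, behavior = beh,
                                 u_ia = innov$ia_u)
          row <- row + 1L
          num[row, ] <- c(rec$ignition_day, rec$spread_day, rec$final_area,
                          rec$duration, rec$prop_high_severity, rec$mean_cbi,
                          rec$cbi_mad, rec$n_crown_days)
          smoldered[row] <- rec$smoldered
          contained[row] <- rec$contained_ia
          scen_idx[row] <- s; rep_idx[row] <- rep_i
          ign_idx[row] <- ign; lvl_idx[row] <- lvl
        }
      }
    }
    if (progress) message(sprintf("  replicate %d/%d done", rep_i,
                                  config$n_replicates))
  }

  tibble::tibble(
    replicate = rep_idx, ignition = ign_idx, level = lvl_idx,
    level_value = config$level_values[lvl_idx],
    level_years = config$level_years[lvl_idx],
    scenario = scen_names[scen_idx],
    ignition_day = as.integer(num[, "ignition_day"]),
    spread_day = as.integer(num[, "spread_day"]),
    smoldered = smoldered, contained_ia = contained,
    final_area = num[, "final_area"],
    duration = as.integer(num[, "duration"]),
    prop_high_severity = num[, "prop_high_severity"],
    mean_cbi = num[, "mean_cbi"], cbi_mad = num[, "cbi_mad"],
    n_crown_days = as.integer(num[, "n_crown_days"]))
}
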