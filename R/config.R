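#' Default run configuration
#'
#' The full nested configuration of a simulation run, as a plain list that
#' round-trips through YAML. All study constants live here rather than in
#' code: the 150-day season, 3-day smolder window, 25% moisture of
#' extinction, 5-m daily extinction rule, 40% slope, engagement delays
#' (4/2/1 h), baseline VPD 1.17 kPa and 100-h load 11.23 Mg/ha, yearly rates
#' 0.00837 kPa/yr and 0.036 Mg/ha/yr, 240-yr spans, the 2.25 CBI
#' high-severity threshold, and the 121-ha containment reporting threshold.
#'
#' @param preset One of `"paper"` (full scale: 1000 ignitions, 40
#'   replicates), `"paper-aridity-small"` (100 ignitions, 1 replicate, VPD
#'   axis), or `"baseline-only"` (single level at baseline conditions).
#' @return A nested list of class `run_config`.
#' @export
default_run_config <- function(preset = c("paper", "paper-aridity-small",
                                          "baseline-only")) {
  preset <- match.arg(preset)
  cfg <- list(
    experiment = list(
      axis = "vpd", n_levels = 25, n_ignitions = 1000, n_replicates = 40,
      span_years = 240, baseline_vpd = 1.17, baseline_load = 11.23,
      vpd_rate = 0.00837, load_rate = 0.036, season_length = 150,
      seed = 1, containment_report_ha = 121
    ),
    weather = unclass(weather_params()),
    fuels = unclass(fuel_complex()),
    severity = unclass(severity_mapping()),
    sim = unclass(sim_params()),
    scenarios = lapply(default_scenarios(), unclass)
  )
  cfg$sim$ia_coef <- as.list(cfg$sim$ia_coef)
  if (preset == "paper-aridity-small") {
    cfg$experiment$n_ignitions <- 100
    cfg$experiment$n_replicates <- 1
  } else if (preset == "baseline-only") {
    cfg$experiment$n_levels <- 1
    cfg$experiment$span_years <- 0
    cfg$experiment$n_replicates <- 1
  }
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration
#'
#' YAML round-trip of a [default_run_config()]-shaped configuration;
#' `read_run_config()` validates the result.
#'
#' @param path File path.
#' @return `read_run_config()` returns a validated `run_config`;
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- structure(yaml::read_yaml(path), class = "run_config")
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param config A `run_config` list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Validate a run configuration
#'
#' Schema and range checks with field-level messages; returns the config
#' invisibly on success.
#'
#' @param config A `run_config` list.
#' @export
validate_run_config <- function(config) {
  problems <- character()
  need <- function(block, fields) {
    if (is.null(config[[block]])) {
      problems <<- c(problems, sprintf("missing block `%s`", block))
      return(FALSE)
    }
    miss <- setdiff(fields, names(config[[block]]))
    if (length(miss) > 0)
      problems <<- c(problems, sprintf("block `%s` missing fields: %s", block,
                                       paste(miss, collapse = ", ")))
    length(miss) == 0
  }
  if (need("experiment", c("axis", "n_levels", "n_ignitions", "n_replicates",
                           "span_years", "baseline_vpd", "baseline_load",
                           "vpd_rate", "load_rate", "season_length", "seed"))) {
    ex <- config$experiment
    if (!ex$axis %in% c("vpd", "fuel_load"))
      problems <- c(problems, "experiment$axis must be 'vpd' or 'fuel_load'")
    for (f in c("n_levels", "n_ignitions", "n_replicates", "season_length"))
      if (!is.numeric(ex[[f]]) || ex[[f]] < 1)
        problems <- c(problems, sprintf("experiment$%s must be >= 1", f))
    for (f in c("baseline_vpd", "baseline_load", "vpd_rate", "load_rate"))
      if (!is.numeric(ex[[f]]) || ex[[f]] <= 0)
        problems <- c(problems, sprintf("experiment$%s must be > 0", f))
  }
  need("weather", c("wind_shape", "wind_scale", "ar_phi", "ar_sd",
                    "fm_a", "fm_b", "fm_c"))
  need("fuels", c("load_1h", "load_10h", "load_100h", "fuelbed_depth",
                  "moisture_of_extinction", "slope"))
  need("severity", c("fl_mid", "fl_scale", "gamma", "high_severity_threshold"))
  need("sim", c("n_angles", "active_hours", "extinguish_m", "smolder_days",
                "ia_coef"))
  if (need("scenarios", character())) {
    for (nm in names(config$scenarios)) {
      sc <- config$scenarios[[nm]]
      miss <- setdiff(c("name", "ceiling", "mid", "slope", "direction",
                        "impossible_above"), names(sc))
      if (length(miss) > 0)
        problems <- c(problems, sprintf("scenario `%s` missing fields: %s", nm,
                                        paste(miss, collapse = ", ")))
      else if (sc$ceiling < 0 || sc$ceiling > 1)
        problems <- c(problems, sprintf("scenario `%s`: ceiling must be in [0, 1]", nm))
    }
  }
  if (length(problems) > 0)
    stop("invalid run config:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  invisible(config)
}

# Rebuild the typed objects an experiment needs from a plain config list.
config_to_experiment <- function(config, seed = NULL) {
  validate_run_config(config)
  ex <- config$experiment
  wp <- do.call(weather_params, config$weather)
  fc <- do.call(fuel_complex,
                config$fuels[names(config$fuels) %in% names(formals(fuel_complex))])
  sv <- do.call(severity_mapping,
                config$severity[names(config$severity) %in%
                                  names(formals(severity_mapping))])
  sm <- config$sim
  sp <- sim_params(n_angles = sm$n_angles, active_hours = sm$active_hours,
                   extinguish_m = sm$extinguish_m,
                   smolder_days = sm$smolder_days,
                   ia_coef = unlist(sm$ia_coef))
  scen <- lapply(config$scenarios, function(sc)
    suppression_scenario(sc$name,
                         engagement_delay =
                           if (is.null(sc$engagement_delay) ||
                               is.na(sc$engagement_delay)) NA
                           else sc$engagement_delay,
                         ceiling = sc$ceiling, mid = sc$mid, slope = sc$slope,
                         direction = sc$direction,
                         impossible_above = sc$impossible_above))
  experiment_config(axis = ex$axis, n_levels = ex$n_levels,
                    n_ignitions = ex$n_ignitions,
                    n_replicates = ex$n_replicates, scenarios = scen,
                    span_years = ex$span_years, baseline_vpd = ex$baseline_vpd,
                    baseline_load = ex$baseline_load, vpd_rate = ex$vpd_rate,
                    load_rate = ex$load_rate,
                    season_length = ex$season_length,
                    weather = wp, fuels = fc, mapping = sv, sim = sp,
                    seed = if (is.null(seed)) ex$seed else seed)
}

#' Run an experiment from a configuration and write its outputs
#'
#' Executes [run_experiment()] for a run configuration, then writes the
#' per-fire record table (`records.csv`), the per-level summaries
#' (`level_summary.csv`), a per-scenario scalar table of growth rates,
#' doubling times, and top-1% shares (`scenario_summary.csv`), and a
#' metadata echo of the config and seed (`metadata.yml`).
#'
#' @param config A `run_config` (list) or path to a YAML config file.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional master-seed override.
#' @param progress Print progress.
#' @return Invisibly, a list with `records`, `levels`, `scenarios` tibbles
#'   and the output paths.
#' @export
run_from_config <- function(config, out_dir, seed = NULL, progress = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  ec <- config_to_experiment(config, seed = seed)
  records <- run_experiment(ec, progress = progress)
  levels <- summarize_levels(records)
  scen <- summarize_scenarios(records)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("records.csv", "level_summary.csv",
                                "scenario_summary.csv", "metadata.yml"))
  utils::write.csv(records, paths[1], row.names = FALSE)
  utils::write.csv(levels, paths[2], row.names = FALSE)
  utils::write.csv(scen, paths[3], row.names = FALSE)
  yaml::write_yaml(list(config = unclass(config), seed = ec$seed,
                        package_version = as.character(utils::packageVersion("firebias")),
                        n_records = nrow(records)), paths[4])
  invisible(list(records = records, levels = levels, scenarios = scen,
                 paths = paths))
}

#' Per-scenario scalar summaries
#'
#' One row per suppression scenario: growth rate of mean burned area along
#' the gradient (delta, %/yr, and doubling time) and the share of total
#' burned area in the largest 1% of fires (pooled over replicates at the
#' baseline level).
#'
#' @param records Fire-record tibble from [run_experiment()].
#' @return A tibble with one row per scenario.
#' @export
summarize_scenarios <- function(records) {
  check_record_columns(records)
  base_lvl <- min(records$level)
  multi_level <- length(unique(records$level)) >= 2
  records |>
    dplyr::group_by(.data$scenario) |>
    dplyr::group_modify(function(d, key) {
      top1 <- top_share(d$final_area[d$level == base_lvl], 0.01)
      if (multi_level) {
        lm_tbl <- d |>
          dplyr::group_by(.data$replicate, .data$level_years) |>
          dplyr::summarise(mean_area = mean(.data$final_area),
                           .groups = "drop")
        gr <- growth_rate(lm_tbl)
        tibble::tibble(delta_pct_yr = 100 * gr$delta,
                       doubling_time_yr = gr$doubling_time,
                       top1_share_pct = 100 * top1)
      } else {
        tibble::tibble(delta_pct_yr = NA_real_, doubling_time_yr = NA_real_,
                       top1_share_pct = 100 * top1)
      }
    }) |>
    dplyr::ungroup()
}

#' Containment curves on an intensity grid
#'
#' Evaluates every scenario's daily containment curve on a log-spaced
#' fireline-intensity grid, for export or plotting.
#'
#' @param scenarios Named list of [suppression_scenario()]s.
#' @param intensity Intensity grid, kW/m.
#' @return A tibble with `scenario`, `intensity`, `prop_suppressed`.
#' @export
containment_curve_table <- function(scenarios = default_scenarios(),
                                    intensity = 10^seq(0, 4.3, length.out = 200)) {
  purrr::map_dfr(scenarios, function(sc)
    tibble::tibble(scenario = sc$name, intensity = intensity,
                   prop_suppressed = containment_fraction(intensity, sc)))
}

#' Recompute summaries from a stored record table
#'
#' Reads a `records.csv` written by [run_from_config()] (or any table with
#' the documented record columns) and recomputes the level and scenario
#' summaries, writing them next to the records when `out_dir` is given.
#'
#' @param records_path Path to a delimited record table.
#' @param out_dir Optional output directory for the summary files.
#' @return List with `levels` and `scenarios` tibbles.
#' @export
summarize_records_file <- function(records_path, out_dir = NULL) {
  if (!file.exists(records_path))
    stop("records file not found: ", records_path, call. = FALSE)
  records <- tibble::as_tibble(utils::read.csv(records_path))
  check_record_columns(records)
  levels <- summarize_levels(records)
  scen <- summarize_scenarios(records)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(levels, file.path(out_dir, "level_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(scen, file.path(out_dir, "scenario_summary.csv"),
                     row.names = FALSE)
  }
  list(levels = levels, scenarios = scen)
}
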