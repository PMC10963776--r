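test_that("ignitions die naturally when the smolder window stays too moist", {
  wx <- make_weather(season_length = 20, fm1 = 0.30, ignition_day = 5)
  fr <- simulate_fire(wx, fuel_complex(), default_scenarios()$none)
  expect_true(fr$smoldered)
  expect_identical(fr$final_area, 0)
  expect_identical(fr$duration, 0L)
  expect_true(is.na(fr$mean_cbi))

  # moisture drops on the third smolder day: spread starts there
  wx2 <- make_weather(season_length = 20, fm1 = c(rep(0.30, 6), rep(0.08, 14)),
                      ignition_day = 5)
  fr2 <- simulate_fire(wx2, fuel_complex(), default_scenarios()$none)
  expect_false(fr2$smoldered)
  expect_identical(fr2$spread_day, 7L)

  # ...but not outside the three-day window
  wx3 <- make_weather(season_length = 20, fm1 = c(rep(0.30, 7), rep(0.08, 13)),
                      ignition_day = 5)
  expect_true(simulate_fire(wx3, fuel_complex(),
                            default_scenarios()$none)$smoldered)
})

test_that("a zero-containment scenario reproduces the unsuppressed fire", {
  zero <- suppression_scenario("zero", NA, ceiling = 0,
                               direction = "regressive")
  set.seed(20)
  wx <- simulate_weather(1.17)
  a <- simulate_fire(wx, fuel_complex(), default_scenarios()$none)
  b <- simulate_fire(wx, fuel_complex(), zero)
  expect_identical(a$final_area, b$final_area)
  expect_identical(a$mean_cbi, b$mean_cbi)
  expect_identical(a$duration, b$duration)
})

test_that("constant-weather unsuppressed growth matches the geometry oracle", {
  n_days <- 8
  wx <- make_weather(season_length = n_days, windspeed = 10, fm1 = 0.07)
  f <- surface_fuels()
  beh <- fire_behavior(f, wx)
  fr <- simulate_fire(wx, f, default_scenarios()$none)

  # accumulated head distance, spread over the rear-focus ellipse
  head_dist <- n_days * beh$ros[1] * 7.5 * 60
  r_final <- head_dist * ellipse_factors(beh$lb[1])
  expect_equal(fr$final_area, polar_area(r_final), tolerance = 1e-9)
  expect_identical(fr$duration, as.integer(n_days))
})

test_that("no fire burns past the end of the season", {
  rec <- baseline_records()
  spread <- dplyr::filter(rec, !smoldered)
  expect_true(all(spread$spread_day + spread$duration - 1 <= 150))
  expect_true(all(spread$spread_day - spread$ignition_day <= 2))
})

test_that("per-record pairing: suppression never increases burned area", {
  rec <- baseline_records()
  wide <- rec |>
    dplyr::select(ignition, scenario, final_area) |>
    tidyr::pivot_wider(names_from = scenario, values_from = final_area)
  expect_true(all(wide$none >= wide$moderate - 1e-9))
  expect_true(all(wide$none >= wide$high - 1e-9))
  expect_true(all(wide$none >= wide$maximum - 1e-9))
  expect_true(all(wide$none >= wide$progressive - 1e-9))
})

test_that("the experiment has factorial cardinality and is reproducible", {
  cfg <- experiment_config(n_levels = 2, n_ignitions = 2, n_replicates = 1,
                           seed = 21)
  rec <- run_experiment(cfg)
  expect_identical(nrow(rec), 2L * 2L * 5L)
  expect_identical(dplyr::n_distinct(rec$scenario), 5L)

  rec2 <- run_experiment(cfg)
  expect_identical(rec, rec2)

  # weather and ignition day are shared across levels and scenarios
  per_ign <- rec |> dplyr::group_by(ignition) |>
    dplyr::summarise(n_days = dplyr::n_distinct(ignition_day))
  expect_true(all(per_ign$n_days == 1))
})

test_that("severity metrics are area-weighted over ring increments", {
  expect_equal(severity_metrics(c(1, 1), c(3, 3)),
               list(prop_high_severity = 1, mean_cbi = 3, cbi_mad = 0))
  expect_equal(severity_metrics(c(2, 2), c(1, 3)),
               list(prop_high_severity = 0.5, mean_cbi = 2, cbi_mad = 1))
  one <- severity_metrics(5, 1.7)
  expect_identical(one$prop_high_severity, 0)
  expect_identical(one$cbi_mad, 0)
  expect_error(severity_metrics(numeric(0), numeric(0)), "positive")
  expect_error(severity_metrics(c(0, 0), c(1, 2)), "positive")
})

test_that("initial-attack containment records the engagement-size fire", {
  wx <- make_weather(season_length = 10, windspeed = 6, fm1 = 0.12, ia_u = 0)
  f <- fuel_complex()
  fr <- simulate_fire(wx, f, default_scenarios()$maximum)
  expect_true(fr$contained_ia)
  expect_identical(fr$duration, 1L)
  beh <- fire_behavior(f, wx)
  r_eng <- beh$ros[1] * 60 * ellipse_factors(beh$lb[1])
  expect_equal(fr$final_area, polar_area(r_eng), tolerance = 1e-9)
  expect_false(is.na(fr$mean_cbi))
})
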