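test_that("growth rate recovers exact exponential growth to machine precision", {
  years <- seq(0, 240, length.out = 25)
  d <- tibble::tibble(level_years = years, mean_area = 100 * 1.05^years)
  fit <- growth_rate(d)
  expect_equal(fit$delta, 0.05, tolerance = 1e-12)
  expect_equal(fit$doubling_time, log(2) / log(1.05), tolerance = 1e-12)
  expect_equal(round(fit$doubling_time), 14)

  # the paper-scale arithmetic: 1.8 %/yr doubles in 39 years
  d2 <- tibble::tibble(level_years = years, mean_area = 1.018^years)
  expect_equal(round(growth_rate(d2)$doubling_time), 39)

  flat <- growth_rate(tibble::tibble(level_years = years, mean_area = 7))
  expect_equal(flat$delta, 0, tolerance = 1e-12)
  expect_identical(flat$doubling_time, Inf)

  expect_error(growth_rate(tibble::tibble(level_years = 1:3,
                                          mean_area = c(1, 0, 2))),
               "positive")
})

test_that("growth rate averages per-replicate fits and tidies", {
  d <- tidyr::expand_grid(replicate = 1:2,
                          level_years = seq(0, 100, by = 10)) |>
    dplyr::mutate(mean_area = ifelse(replicate == 1, 1.02, 1.04)^level_years)
  fit <- growth_rate(d)
  expect_equal(fit$per_replicate, c(0.02, 0.04), tolerance = 1e-10)
  expect_equal(fit$delta, 0.03, tolerance = 1e-10)

  td <- tidy(fit)
  expect_identical(td$term, c("delta", "doubling_time"))
  expect_equal(td$estimate[1], 0.03, tolerance = 1e-10)
  gl <- glance(fit)
  expect_identical(gl$n_replicates, 2L)
  expect_identical(gl$n_levels, 11L)
})

test_that("Lorenz curves and top shares capture burned-area inequality", {
  eq <- lorenz_curve(rep(4, 50))
  expect_equal(eq$p_area, eq$p_fires, tolerance = 1e-12)
  expect_true(all(diff(eq$p_area) >= 0))
  expect_equal(eq$p_area[length(eq$p_area)], 1)
  # convexity: increments never decrease in the ranked order
  expect_true(all(diff(diff(lorenz_curve(c(1, 2, 3, 10, 50))$p_area)) > -1e-12))

  expect_equal(top_share(rep(1, 100), 0.01), 0.01, tolerance = 1e-12)
  expect_equal(top_share(c(rep(0, 99), 42), 0.01), 1)
  expect_equal(top_share(c(1, 1, 1, 97), 0.25), 0.97, tolerance = 1e-12)
  expect_error(lorenz_curve(numeric(0)), "positive")
  expect_error(top_share(rep(0, 10)), "positive")
})

test_that("replicate confidence intervals follow the t distribution", {
  same <- replicate_ci(rep(2.5, 8))
  expect_equal(same$lo, 2.5)
  expect_equal(same$hi, 2.5)

  two <- replicate_ci(c(0, 1))
  expect_equal(two$mean, 0.5)
  expect_equal(two$hi - two$mean, qt(0.975, 1) * sd(c(0, 1)) / sqrt(2),
               tolerance = 1e-12)

  one <- replicate_ci(3)
  expect_identical(one$lo, NA_real_)

  set.seed(30)
  cover <- vapply(1:400, function(i) {
    ci <- replicate_ci(rnorm(40, mean = 1))
    ci$lo <= 1 && ci$hi >= 1
  }, logical(1))
  expect_gt(mean(cover), 0.90)
  expect_lt(mean(cover), 0.99)
})

test_that("years-equivalent inverts the no-suppression curve", {
  curve <- tibble::tibble(level_value = seq(1.17, 3.17, length.out = 25),
                          metric = seq(1, 2, length.out = 25))
  # observed equal to the baseline metric: zero years
  expect_equal(years_equivalent(curve, 1, rate = 0.00837), 0)
  # linear curve: +0.85 kPa of VPD at 0.00837 kPa/yr is about 102 years
  obs <- 1 + (0.85 / 2)
  expect_equal(years_equivalent(curve, obs, rate = 0.00837), 0.85 / 0.00837,
               tolerance = 1e-9)
  expect_equal(round(years_equivalent(curve, obs, rate = 0.00837)), 102)
  # a negative offset maps to years in the past: -0.49 Mg/ha at
  # 0.036 Mg/ha/yr is about 14 years
  curve_load <- tibble::tibble(level_value = seq(2, 20, length.out = 25),
                               metric = seq(2, 20, length.out = 25) / 10)
  yr <- years_equivalent(curve_load, (11.23 - 0.49) / 10, rate = 0.036,
                         baseline = 11.23)
  expect_equal(yr, -0.49 / 0.036, tolerance = 1e-9)
  expect_equal(round(abs(yr)), 14)
  # observations beyond the curve are clamped with a warning
  expect_warning(years_equivalent(curve_load, 99, rate = 0.036),
                 "extrapolat")

  wiggly <- tibble::tibble(level_value = 1:6, metric = c(1, 2, 3, 2.5, 4, 5))
  expect_warning(years_equivalent(wiggly, 2.2, rate = 1), "monotone")
})

test_that("level summaries aggregate by scenario, level, and replicate", {
  rec <- baseline_records()
  lev <- summarize_levels(rec)
  expect_identical(nrow(lev), 5L)
  expect_true(all(c("mean_area", "mean_cbi", "prop_high_severity",
                    "cbi_mad") %in% names(lev)))
  none <- lev[lev$scenario == "none", ]
  expect_true(none$mean_cbi >= 0 && none$mean_cbi <= 3)
  expect_error(summarize_levels(dplyr::select(rec, -mean_cbi)), "missing")
  expect_error(summarize_levels(rec[0, ]), "empty")
})
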