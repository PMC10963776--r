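test_that("surface spread matches the hand-calculated equation chain", {
  f <- fuel_complex()
  for (case in list(c(0.08, 0.09, 0.10, 1.0, 1.0, 10),
                    c(0.06, 0.07, 0.08, 0.6, 0.9, 25),
                    c(0.15, 0.16, 0.17, 1.5, 1.2, 5))) {
    got <- surface_spread(f, case[1], case[2], case[3], case[4], case[5],
                          case[6])
    want <- rothermel_by_hand(f, case[1], case[2], case[3], case[4], case[5],
                              case[6])
    expect_equal(got$ros, want$ros, tolerance = 1e-4)
    expect_equal(got$intensity, want$intensity, tolerance = 1e-4)
  }
})

test_that("zero-wind zero-slope spread equals the no-wind base rate", {
  f <- fuel_complex(slope = 0)
  got <- surface_spread(f, 0.08, 0.09, 0.10, 1, 1, 0)
  want <- rothermel_by_hand(f, 0.08, 0.09, 0.10, 1, 1, 0)
  expect_equal(got$ros, want$ros, tolerance = 1e-6)
})

test_that("spread stops at the moisture of extinction", {
  f <- fuel_complex()
  out <- surface_spread(f, c(0.24, 0.25, 0.30), 0.25, 0.25, 1, 1, 10)
  expect_gt(out$ros[1], 0)
  expect_identical(out$ros[2:3], c(0, 0))
  expect_identical(out$intensity[2:3], c(0, 0))
})

test_that("spread responds monotonically to wind and dead fuel moisture", {
  f <- fuel_complex()
  set.seed(8)
  for (i in 1:25) {
    m1 <- runif(1, 0.03, 0.2)
    w <- sort(runif(2, 0, 40))
    r <- surface_spread(f, m1, m1 + 0.01, m1 + 0.02, 1, 1, w)
    expect_lte(r$ros[1], r$ros[2])

    wind <- runif(1, 0, 30)
    ms <- sort(runif(2, 0.03, 0.24))
    r2 <- surface_spread(f, ms, ms + 0.01, ms + 0.02, 1, 1, wind)
    expect_gte(r2$ros[1], r2$ros[2])
  }
})

test_that("fireline intensity equals heat per unit area times spread rate", {
  f <- fuel_complex()
  out <- surface_spread(f, 0.07, 0.08, 0.09, 0.8, 1.0, c(0, 8, 16, 32))
  expect_equal(out$intensity, out$hpua * out$ros / 60, tolerance = 1e-12)
})

test_that("empty fuel bed gives zero spread without error", {
  f <- fuel_complex(load_1h = 0, load_10h = 0, load_100h = 0,
                    load_live_herb = 0, load_live_woody = 0)
  out <- surface_spread(f, 0.08, 0.09, 0.1, 1, 1, 10)
  expect_identical(out$ros, 0)
})

test_that("crown transition follows the critical-intensity criterion", {
  f <- fuel_complex()
  fmc <- 1.0
  i0 <- (0.01 * f$canopy_base_height * (460 + 25.9 * fmc * 100))^1.5
  surf <- tibble::tibble(ros = c(2, 2), intensity = c(i0 * 0.999, i0 * 1.001),
                         flame_length = byram_flame_length(c(i0, i0)),
                         hpua = c(15000, 15000))
  out <- crown_transition(surf, f, wind = c(10, 10), m1 = c(0.08, 0.08),
                          canopy_fm = fmc)
  expect_identical(out$fire_type[1], "surface")
  expect_true(out$fire_type[2] %in% c("passive_crown", "active_crown"))
  expect_gt(out$intensity[2], surf$intensity[2])

  # unreachable canopy: no crowning at any realistic surface intensity
  tall <- fuel_complex(canopy_base_height = 500)
  out2 <- crown_transition(tibble::tibble(ros = 5, intensity = 5e4,
                                          flame_length = 10, hpua = 2e4),
                           tall, 40, 0.05, 1.0)
  expect_identical(out2$fire_type, "surface")

  # active crown fire spreads at least as fast as the surface fire and is
  # strictly more intense
  windy <- crown_transition(tibble::tibble(ros = 3, intensity = 2e4,
                                           flame_length = 12, hpua = 15000),
                            f, wind = 40, m1 = 0.04, canopy_fm = 0.8)
  expect_identical(windy$fire_type, "active_crown")
  expect_gte(windy$ros, 3)
  expect_gt(windy$intensity, 2e4)
})

test_that("Byram flame length follows the metric power law", {
  expect_identical(byram_flame_length(0), 0)
  expect_equal(byram_flame_length(1000), 0.0775 * 1000^0.46, tolerance = 1e-12)
  expect_equal(round(byram_flame_length(1000), 2), 1.86)
  x <- byram_flame_length(c(10, 100, 1000, 10000))
  expect_true(all(diff(x) > 0))
  expect_error(byram_flame_length(-1), ">= 0")
})
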