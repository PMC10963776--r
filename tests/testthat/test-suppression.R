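test_that("containment curves respect direction, limits, and impossibility", {
  sc <- default_scenarios()
  ii <- 10^seq(-1, 5, length.out = 400)

  expect_identical(containment_fraction(ii, sc$none), rep(0, length(ii)))

  for (s in sc[c("moderate", "high", "maximum")]) {
    below <- ii < s$impossible_above
    expect_true(all(diff(containment_fraction(ii[below], s)) <= 0))
    expect_true(all(containment_fraction(ii[!below], s) == 0))
  }
  # near-total suppression of low-intensity fire under Maximum
  expect_gt(containment_fraction(10, sc$maximum), 0.95)

  pr <- containment_fraction(ii, sc$progressive)
  below <- ii < sc$progressive$impossible_above
  expect_true(all(diff(pr[below]) >= 0))
  expect_true(all(pr[!below] == 0))

  expect_error(containment_fraction(-5, sc$maximum), ">= 0")
})

test_that("regressive curves are pointwise ordered by aggressiveness", {
  sc <- default_scenarios()
  ii <- 10^seq(-1, 4.5, length.out = 500)
  f_mod <- containment_fraction(ii, sc$moderate)
  f_high <- containment_fraction(ii, sc$high)
  f_max <- containment_fraction(ii, sc$maximum)
  expect_true(all(f_max >= f_high))
  expect_true(all(f_high >= f_mod))
  expect_true(all(f_mod >= 0))
})

test_that("initial-attack probability matches its logistic and is monotone", {
  co <- c(b0 = 24.0, b_intensity = 3.1, b_size = 1.5)
  ii <- c(10, 100, 1000, 10000); aa <- c(0.1, 1, 10)
  grid <- expand.grid(i = ii, a = aa)
  p <- initial_attack_probability(grid$i, grid$a, co)
  expect_equal(p, plogis(24.0 - 3.1 * log1p(grid$i) - 1.5 * log1p(grid$a)),
               tolerance = 1e-12)
  # non-increasing in intensity at fixed size, and in size at fixed intensity
  expect_true(all(diff(initial_attack_probability(ii, 1, co)) < 0))
  expect_true(all(diff(initial_attack_probability(500, aa, co)) < 0))
  expect_lt(initial_attack_probability(1e6, 1, co), 1e-6)
  expect_error(initial_attack_probability(-1, 1), ">= 0")
})

test_that("earlier engagement gives smaller fires and no lower containment", {
  sc_max <- default_scenarios()$maximum    # 1 h
  sc_high <- default_scenarios()$high      # 2 h
  a1 <- attempt_initial_attack(2, 800, 2.5, sc_max, u = 0.5)
  a2 <- attempt_initial_attack(2, 800, 2.5, sc_high, u = 0.5)
  expect_lt(a1$size_ha, a2$size_ha)
  expect_gte(a1$prob, a2$prob)
  expect_error(attempt_initial_attack(2, 800, 2.5, default_scenarios()$none),
               "engagement delay")
  expect_error(attempt_initial_attack(2, 800, 2.5,
                                      default_scenarios()$progressive),
               "engagement delay")
})

test_that("initial-attack containment frequency matches its probability", {
  sc <- default_scenarios()$maximum
  # pick a day-one state with containment probability well inside (0, 1)
  p <- attempt_initial_attack(5, 2500, 3, sc, u = 0)$prob
  expect_true(p > 0.05 && p < 0.95)
  set.seed(10)
  hits <- vapply(runif(2000), function(u)
    attempt_initial_attack(5, 2500, 3, sc, u = u)$contained, logical(1))
  expect_lt(abs(mean(hits) - p), 3 * sqrt(p * (1 - p) / 2000))

  # certain containment in the low-intensity regime
  expect_true(attempt_initial_attack(0.05, 1, 1.2, sc, u = 0.999999)$contained)
})

test_that("suppression reduces per-angle increments by the local fraction", {
  sc <- default_scenarios()
  g <- ellipse_factors(4)
  inc <- 450 * 3 * g
  local_i <- perimeter_intensity(5000, g)

  expect_identical(apply_suppression(inc, local_i, sc$none), inc)

  total <- suppression_scenario("wall", 1, ceiling = 1, mid = 99, slope = 10,
                                direction = "regressive",
                                impossible_above = Inf)
  expect_equal(apply_suppression(inc, local_i, total), rep(0, length(inc)),
               tolerance = 1e-12)

  # under Maximum, low-intensity flanks lose a larger share than the head
  kept <- apply_suppression(inc, local_i, sc$maximum) / inc
  expect_gt(kept[which.max(local_i)], kept[which.min(local_i)])
  expect_error(apply_suppression(-inc, local_i, sc$maximum), ">= 0")
})
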