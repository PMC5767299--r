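test_that("constant profiles return their temperature on every day", {
  p <- climate_const(25)
  expect_equal(daily_temperature(p, c(1, 40, 365, 400)), rep(25, 4))
})

test_that("sinusoidal profiles attain their min, max and annual mean", {
  for (p in list(climate_med(), climate_opt())) {
    t <- daily_temperature(p, 1:365)
    expect_equal(min(t), p$t_min, tolerance = 0.01)
    expect_equal(max(t), p$t_max, tolerance = 0.01)
    expect_lt(abs(mean(t) - p$t_mean), 0.2)
    expect_true(all(t >= p$t_min - 1e-9 & t <= p$t_max + 1e-9))
  }
})

test_that("multi-year runs repeat the annual pattern exactly", {
  p <- climate_med()
  expect_equal(daily_temperature(p, 1:365), daily_temperature(p, 366:730))
})

test_that("invalid day or inconsistent anchors are rejected", {
  expect_error(daily_temperature(climate_med(), 0))
  expect_error(climate_profile("sinusoidal", t_min = 15, t_max = 10, t_mean = 12))
})

test_that("activity scalar has the optimum plateau and winter cutoff", {
  expect_equal(activity_scalar(c(20, 22.5, 25)), c(1, 1, 1))
  expect_lte(activity_scalar(11), 0.05)
  a27 <- activity_scalar(27)
  expect_gt(a27, 0.8); expect_lt(a27, 1)
  # continuity and unimodality on a fine grid
  t <- seq(5, 40, by = 0.1)
  a <- activity_scalar(t)
  expect_true(all(a >= 0 & a <= 1))
  expect_true(all(diff(a[t <= 20]) >= -1e-9))   # rising on the cold side
  expect_true(all(diff(a[t >= 25]) <= 1e-9))    # falling on the hot side
  expect_true(all(abs(diff(a)) < 0.05))         # no jumps
})

test_that("temperature series export is day-indexed", {
  ts <- temperature_series(climate_opt(), 1:365)
  expect_named(ts, c("day", "temp_c"))
  expect_equal(nrow(ts), 365)
})
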