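test_that("stage durations hit their bounds at the thermal anchors", {
  expect_equal(stage_duration("egg", 30), 3)
  expect_equal(stage_duration("egg", 13), 11)
  expect_equal(stage_duration("larva", c(30, 13)), c(8, 55))
  expect_equal(stage_duration("pupa", c(30, 13)), c(9, 67))
  expect_equal(stage_duration("pupa", 21.5), 38)
  # monotone non-increasing in temperature, suspended below the cutoff
  t <- seq(11, 34, by = 0.5)
  for (stg in c("egg", "larva", "pupa")) {
    expect_true(all(diff(stage_duration(stg, t)) <= 1e-9))
  }
  expect_equal(stage_duration("larva", 10), Inf)
  expect_error(stage_duration("imago", 25))
})

test_that("stage survival stays within its bounds, maximal on the plateau", {
  p <- stage_params()
  t <- seq(10, 40, by = 0.5)
  for (i in seq_len(nrow(p))) {
    s <- stage_survival(p$stage[i], t)
    expect_true(all(s >= p$survival_min[i] - 1e-9 & s <= p$survival_max[i] + 1e-9))
    expect_equal(stage_survival(p$stage[i], 22.5), p$survival_max[i])
    expect_equal(stage_survival(p$stage[i], 13), p$survival_min[i])
  }
  # a stage completed at constant temperature pays exactly its cumulative
  # survival through the daily-rate formulation
  dur <- stage_duration("egg", 25)
  expect_equal(stage_daily_survival("egg", 25)^dur, stage_survival("egg", 25))
})

test_that("Gompertz calibration gives mean 79.1 d and truncation at 170 d", {
  g <- gompertz_params()
  expect_equal(g$mean_lifespan, 79.1, tolerance = 1e-6)
  expect_equal(g$truncation_age, 170)
  expect_equal(intrinsic_hazard(170), 1)
  expect_equal(intrinsic_survival(171), 0)
  expect_gt(intrinsic_hazard(50), intrinsic_hazard(10))
  expect_error(intrinsic_hazard(-1))
  # integral of the survival curve reproduces the mean
  expect_equal(sum(intrinsic_survival(0:169)), 79.1, tolerance = 0.05)
})

test_that("expected longevity under 2% extrinsic risk matches the anchors", {
  cal <- demography_calibration()
  expect_equal(cal$expected_longevity_extrinsic_2pct$t20, 35.1, tolerance = 1e-6)
  expect_equal(cal$expected_longevity_extrinsic_2pct$t25, 26.7, tolerance = 1e-6)
  expect_equal(cal$expected_longevity_extrinsic_2pct$t30, 16.9, tolerance = 1e-6)
  # removing extrinsic mortality lengthens life everywhere
  expect_gt(cal$expected_longevity_no_extrinsic$t25,
            cal$expected_longevity_extrinsic_2pct$t25)
})

test_that("maturation takes 16/9/6 calendar days at 20/25/30 C", {
  expect_equal(ceiling(11 / maturation_rate(c(20, 25, 30))), c(16, 9, 6))
  expect_equal(maturation_rate(22.5), 1)
  expect_equal(maturation_rate(11), 0)
})

test_that("maturity bands split at physiological ages 11, 46 and 76", {
  expect_equal(as.character(maturity_category(c(5, 10.9, 11, 45, 46, 75, 76, 200))),
               c("young", "young", "mature", "mature", "old", "old",
                 "very_old", "very_old"))
  expect_error(maturity_category(-2))
})

test_that("immature cohorts transition with the expected thinning", {
  set.seed(1)
  # a large egg cohort at the optimum loses ~10% crossing into the larval
  # stage (survival 0.90 at suitability 1)
  coh <- tibble::tibble(sector = 1L, stage = 1L, count = 100000L,
                        progress = 0, suitability = 1)
  repeat {
    adv <- advance_immatures(coh, 22.5)
    coh <- adv$cohorts
    if (any(coh$stage == 2L)) break
  }
  expect_equal(coh$count[coh$stage == 2L] / 1e5, 0.90, tolerance = 0.01)

  # pupae emerging at the optimum: survival 0.70 times the 30% in-soil loss
  coh <- tibble::tibble(sector = 1L, stage = 3L, count = 100000L,
                        progress = 0, suitability = 1)
  emerged <- 0L
  repeat {
    adv <- advance_immatures(coh, 22.5)
    coh <- adv$cohorts
    if (nrow(adv$emerged)) { emerged <- sum(adv$emerged$count); break }
  }
  expect_equal(emerged / 1e5, 0.70 * 0.70, tolerance = 0.01)
})

test_that("a cohort on the brink of completion transitions the next day", {
  set.seed(2)
  coh <- tibble::tibble(sector = 1L, stage = 1L, count = 1000L,
                        progress = 0.99, suitability = 1)
  adv <- advance_immatures(coh, 25)
  expect_true(all(adv$cohorts$stage == 2L))
})

test_that("emergence is staggered with 75% in the first ten days", {
  set.seed(3)
  expect_equal(nrow(emergence_schedule(0L, 1L)), 0L)
  sch <- emergence_schedule(10000L, 1L)
  expect_equal(sum(sch$count), 10000L)
  span <- max(sch$day) - min(sch$day) + 1L
  expect_gte(span, 25L); expect_lte(span, 40L)
  frac10 <- sum(sch$count[sch$day <= 10]) / 10000
  expect_equal(frac10, 0.75, tolerance = 0.02)
})
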