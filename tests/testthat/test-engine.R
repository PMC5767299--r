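test_that("invasion initialisation places the propagule as configured", {
  cfg <- scenario_invasion("farm", "med", landscape_seed = 1)
  set.seed(1)
  st <- initialize_invasion(cfg)
  expect_equal(sum(st$cohorts$count), 200L)
  expect_equal(st$cohorts$stage, 2L)
  expect_equal(cfg$start_day_of_year, 90L)
  expect_equal(cfg$landscape$cover[cfg$origin_sector], "host")
  # the same seed reproduces the initial state exactly
  set.seed(1); st2 <- initialize_invasion(cfg)
  expect_identical(st$cohorts, st2$cohorts)
})

test_that("an empty population advances without events", {
  cfg <- scenario_validation(25, n_females = 0L, duration_days = 5L)
  r <- run_simulation(cfg, seed = 1)
  expect_equal(r$daily$adults, rep(0L, nrow(r$daily)))
  expect_equal(sum(r$daily$catches), 0L)
})

test_that("identical configuration and seed give bit-identical records", {
  cfg <- scenario_invasion("urban1", "med", landscape_seed = 2,
                           duration_days = 150L)
  a <- run_simulation(cfg, seed = 42)
  b <- run_simulation(cfg, seed = 42)
  expect_identical(a$daily, b$daily)
  expect_identical(a$females, b$females)
  expect_identical(a$presence, b$presence)
})

test_that("every female ever alive is accounted for by exactly one fate", {
  cfg <- scenario_validation(25, n_females = 300L, duration_days = 120L)
  r <- run_simulation(cfg, seed = 3)
  expect_equal(nrow(r$females), 300L)
  fates <- table(r$females$fate)
  expect_equal(sum(fates), 300L)
  expect_true(all(names(fates) %in%
    c("alive", "dead_intrinsic", "dead_extrinsic", "trapped", "emigrated")))
  # each on-site female logs exactly one presence-day per day; females
  # captured during the day logged presence before removal
  expect_equal(sum(r$presence), sum(r$daily$adults) + sum(r$daily$catches))
})

test_that("no adult outlives the 170-day truncation and no female exceeds 742 eggs", {
  cfg <- scenario_validation(25, extrinsic_risk = 0, n_females = 500L,
                             duration_days = 175L)
  r <- run_simulation(cfg, seed = 4)
  died <- r$females$fate %in% c("dead_intrinsic", "dead_extrinsic")
  expect_true(all(r$females$age_at_death[died] <= 170))
  expect_true(all(r$females$cumulative_eggs <= 742))
  # oviposition disabled: no spontaneous generation
  expect_equal(nrow(r$females), 500L)
  expect_equal(sum(r$daily$eggs), 0L)
})

test_that("establishment halts a replicate before the horizon", {
  cfg <- scenario_invasion("farm", "const25", landscape_seed = 1,
                           establishment_threshold = 300)
  r <- run_simulation(cfg, seed = 5)
  expect_equal(r$termination, "established")
  expect_lt(r$termination_day, 700L)
  expect_gte(r$daily$female_equiv[r$termination_day], 300)
})

test_that("replicate series are deterministic in the master seed", {
  cfg <- scenario_validation(25, n_females = 100L, duration_days = 60L)
  a <- run_replicates(cfg, n = 3, master_seed = 9)
  b <- run_replicates(cfg, n = 3, master_seed = 9)
  expect_identical(lapply(a$runs, `[[`, "daily"), lapply(b$runs, `[[`, "daily"))
  expect_equal(length(a$runs), 3L)
})

test_that("presence statistics follow their counting definitions", {
  m <- matrix(0, 40, 40)
  m[20, 20] <- 100
  ps <- presence_statistics(m, release_sector = (19 * 40) + 19 + 1)
  expect_equal(ps$area_ha, 0.0625)
  expect_equal(ps$radius_m, 0)
  # uniform presence over 800 sectors: ceiling(0.9 * 800) = 720 sectors
  m2 <- matrix(0, 40, 40)
  m2[1:20, ] <- 1
  ps2 <- presence_statistics(m2, release_sector = 1, q = 0.9)
  expect_equal(ps2$area_ha, 720 * 0.0625)
  expect_error(presence_statistics(matrix(0, 40, 40), 1))
})

test_that("the 3-sigma control check accepts and rejects as defined", {
  expect_true(three_sigma_check(10, 1, 10))
  expect_true(three_sigma_check(10, 1, 12.9))
  expect_false(three_sigma_check(10, 1, 14))
  expect_error(three_sigma_check(10, -1, 10))
})

test_that("detection summary reports zero detection without catches", {
  cfg <- scenario_validation(25, n_females = 0L, duration_days = 10L)
  reps <- run_replicates(cfg, n = 2, master_seed = 1)
  s <- detection_summary(reps)
  expect_equal(s$detection_pct, 0)
  expect_true(is.na(s$first_detection_day_mean))
  per <- attr(s, "per_replicate")
  expect_equal(nrow(per), 2L)
})

test_that("tidy and glance methods return the documented shapes", {
  cfg <- scenario_validation(25, n_females = 50L, duration_days = 40L)
  reps <- run_replicates(cfg, n = 2, master_seed = 2)
  td <- tidy(reps)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2L)
  gl <- glance(reps)
  expect_equal(nrow(gl), 1L)
  expect_s3_class(tidy(reps$runs[[1]]), "tbl_df")
})
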