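test_that("bait efficacy declines 0.5% per day and resets on re-baiting", {
  expect_equal(bait_efficacy(0), 1)
  expect_equal(bait_efficacy(1) / bait_efficacy(0), 0.995)
  expect_equal(bait_efficacy(60), 0.740, tolerance = 0.001 / 0.740)
  expect_error(bait_efficacy(-1))
})

test_that("trap servicing keeps bait age below the 60-day cycle", {
  traps <- init_traps(place_validation_traps(homogeneous_landscape()))
  ages <- vapply(1:180, function(d) service_traps(traps, d)$bait_age[1], integer(1))
  expect_true(all(ages <= 59L))
  expect_equal(sum(ages == 0L), 3L)        # three fresh baits in 180 days
  expect_equal(ages[61], 0L)
})

test_that("female responsiveness follows the age anchors", {
  expect_equal(female_responsiveness(0), 0.40)
  expect_equal(max(female_responsiveness(seq(0, 170, by = 0.5))), 1.00)
  expect_equal(female_responsiveness(45), 0.50)
  expect_equal(female_responsiveness(120), 0.15, tolerance = 0.02 / 0.15)
})

test_that("capture is confined to the trap sector at the 5% base risk", {
  ls <- place_validation_traps(homogeneous_landscape())
  traps <- service_traps(init_traps(ls), 1)
  set.seed(9)
  # females far from any trap are never captured
  away <- attempt_capture(rep(1L, 1000), rep(15, 1000), traps)
  expect_false(any(away$captured))
  # a peak-responsive female in a trap sector is captured at 5% per trial
  n <- 100000
  hit <- attempt_capture(rep(traps$sector[1], n), rep(15, n), traps)
  expect_equal(mean(hit$captured), 0.05, tolerance = 0.002 / 0.05)
  expect_true(all(hit$trap_id[hit$captured] == traps$trap_id[1]))
})

test_that("per-trial capture probability never exceeds the 5% base risk", {
  ages <- seq(0, 170, by = 1)
  p <- 0.05 * bait_efficacy(0) * female_responsiveness(ages)
  expect_true(all(p <= 0.05 + 1e-12))
  expect_true(all(0.05 * bait_efficacy(0:59) <= 0.05 + 1e-12))
})
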