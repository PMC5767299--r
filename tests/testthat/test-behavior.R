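test_that("the fecundity envelope integrates to the lifetime total", {
  env <- fecundity_envelope(1:170)
  expect_equal(sum(env), 742, tolerance = 1e-9)
  expect_true(all(env >= 0 & env <= 16))
  expect_equal(max(env), 16)
  peak_ages <- which(env == 16)
  expect_true(all(peak_ages >= 20 & peak_ages <= 35))
  expect_true(all(fecundity_envelope(1:10) == 0))
})

test_that("daily fecundity draws are clipped, zero for young, capped at 742", {
  set.seed(4)
  draws <- potential_daily_fecundity(rep(25, 5000), 22.5, cumulative_eggs = 0)
  expect_true(all(draws >= 0 & draws <= 16))
  expect_true(all(potential_daily_fecundity(rep(5, 100), 22.5) == 0))
  near_cap <- potential_daily_fecundity(rep(25, 100), 22.5,
                                        cumulative_eggs = 740)
  expect_true(all(near_cap <= 2))
})

test_that("crowding leaves low infestation untouched and halves laying at full", {
  expect_equal(crowding_factor(c(0, 0.2, 0.3)), c(1, 1, 1))
  expect_equal(crowding_factor(1), 0.5)
  i <- seq(0.3, 1, by = 0.05)
  expect_true(all(diff(crowding_factor(i)) < 0))
})

test_that("oviposition needs fruit and tracks the acceptance factors", {
  set.seed(5)
  expect_true(all(oviposit(rep(10L, 100), fruit_fraction = 0) == 0L))
  full <- oviposit(rep(16L, 2000), fruit_fraction = 1, infestation = 0.1)
  expect_equal(mean(full) / 16, 1, tolerance = 0.02)
  crowded <- oviposit(rep(16L, 2000), fruit_fraction = 1, infestation = 1)
  expect_equal(mean(crowded) / 16, 0.5, tolerance = 0.05)
  expect_error(oviposit(-1L, 1))
})

test_that("females stay put below the activity cutoff", {
  set.seed(6)
  mv <- daily_relocation(sector = rep(820L, 50), phys_age = rep(20, 50),
                         attractiveness = rep(50, 1600), temperature = 10)
  expect_equal(mv$sector, rep(820L, 50))
  expect_false(any(mv$emigrated))
})

test_that("movement is isotropic over a uniform attractiveness field", {
  # under uniform attractiveness the lattice symmetries make the four
  # orthogonal neighbours equally likely, and likewise the four diagonals
  set.seed(7)
  params <- movement_params(mean_hops = 1, hop_dispersion = Inf,
                            persistence = c(young = 0, mature = 0,
                                            old = 0, very_old = 0))
  n <- 40000
  mv <- daily_relocation(sector = rep(820L, n), phys_age = rep(20, n),
                         attractiveness = rep(50, 1600), temperature = 25,
                         params = params)
  row0 <- (820L - 1L) %/% 40L; col0 <- (820L - 1L) %% 40L
  dr <- (mv$sector - 1L) %/% 40L - row0
  dc <- (mv$sector - 1L) %% 40L - col0
  ortho <- table(paste(dr, dc)[abs(dr) + abs(dc) == 1L])
  diag <- table(paste(dr, dc)[abs(dr) == 1L & abs(dc) == 1L])
  expect_equal(length(ortho), 4L)
  expect_equal(length(diag), 4L)
  expect_gt(stats::chisq.test(ortho)$p.value, 0.001)
  expect_gt(stats::chisq.test(diag)$p.value, 0.001)
  # no directional drift
  expect_lt(abs(mean(dr)), 0.02)
  expect_lt(abs(mean(dc)), 0.02)
})

test_that("boundary exchange respects the 1:0.25 in/out balance", {
  set.seed(8)
  expect_equal(boundary_exchange(0L), 0L)
  expect_equal(boundary_exchange(100L, immigration = FALSE), 0L)
  imm <- replicate(400, boundary_exchange(100L))
  expect_equal(mean(imm), 25, tolerance = 0.05)
})

test_that("movement pace rises with temperature through 30 C", {
  expect_equal(movement_pace(25), 1)
  expect_equal(movement_pace(10), 0)
  p <- movement_pace(c(15, 20, 25, 30))
  expect_true(all(diff(p) > 0))
})
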