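test_that("host table carries the packaged trait defaults", {
  h <- host_table()
  expect_equal(h$suitability[1:4], c(0.60, 0.70, 0.90, 0.80))
  expect_equal(h$attractiveness_max[1:4], c(70, 90, 100, 65))
  expect_equal(h$harvest_day[1:4], c(90L, 170L, 250L, 350L))
  expect_equal(h$harvest_accuracy[1:4], c(0.65, 0.75, 0.80, 0.70))
  expect_true(all(h$attractiveness_min <= h$attractiveness_max))
})

test_that("host phenology peaks at harvest and rests at the minimum outside", {
  h <- host_table()
  h3 <- h[h$host_id == 3L & !is.na(h$host_id), ]
  at_peak <- daily_host_state(h3, h3$harvest_day)
  expect_equal(at_peak$attractiveness, 100)
  expect_equal(at_peak$fruit_fraction, 1)
  h1 <- h[h$host_id == 1L & !is.na(h$host_id), ]
  far <- daily_host_state(h1, 250)   # far outside host 1's window
  expect_equal(far$attractiveness, 25)
  expect_equal(far$fruit_fraction, 0)
})

test_that("non-host attractiveness oscillates within 13-29% with no fruit", {
  nh <- host_table()[5, ]
  st <- daily_host_state(nh, 1:365)
  expect_true(all(st$attractiveness >= 13 & st$attractiveness <= 29))
  expect_true(all(st$fruit_fraction == 0))
})

test_that("phenology is periodic and bounded; host windows jointly span the year", {
  hosts <- host_table()[1:4, ]
  fruit_any <- rep(FALSE, 365)
  for (i in 1:4) {
    st <- daily_host_state(hosts[i, ], 1:365)
    st2 <- daily_host_state(hosts[i, ], 366:730)
    expect_equal(st$fruit_fraction, st2$fruit_fraction)
    expect_true(all(st$fruit_fraction >= 0 & st$fruit_fraction <= 1))
    fruit_any <- fruit_any | st$fruit_fraction > 0.02
  }
  expect_gt(mean(fruit_any), 0.95)
})

test_that("harvest removes the stated share of fruit and is idempotent on none", {
  ls <- homogeneous_landscape(host_id = 3L)
  st <- landscape_phenology(ls, 250)    # host 3 harvest day: fruit at peak 1.0
  expect_equal(max(st$fruit_fraction), 1)
  hv <- apply_harvest(st, ls, 250)
  expect_equal(hv$fruit_fraction, st$fruit_fraction * 0.20)
  # a host-4 sector with fruit 0.5 on its harvest day keeps 30%
  ls4 <- homogeneous_landscape(host_id = 4L)
  st4 <- landscape_phenology(ls4, 350)
  st4$fruit_fraction <- 0.5
  expect_equal(apply_harvest(st4, ls4, 350)$fruit_fraction, rep(0.15, nrow(ls4)))
  # idempotent on sectors without fruit
  st0 <- st4; st0$fruit_fraction <- 0
  expect_equal(apply_harvest(st0, ls4, 350)$fruit_fraction, rep(0, nrow(ls4)))
})

test_that("landscape presets realise their cover fractions", {
  farm <- generate_landscape("farm", seed = 1)
  expect_equal(nrow(farm), 1600L)
  expect_equal(mean(farm$cover == "host"), 0.80)
  expect_equal(mean(farm$cover == "non_host"), 0.20)
  expect_equal(as.integer(table(farm$host_id)), rep(320L, 4))

  u4 <- generate_landscape("urban4", seed = 2)
  expect_lt(abs(mean(u4$cover == "bare") - 0.80), 0.02)
  expect_lt(abs(mean(u4$cover == "host") - 0.10), 0.02)
  counts <- table(u4$host_id)
  expect_lt(max(counts) - min(counts), 0.25 * mean(counts) + 2)

  expect_error(site_spec(50, 30, 30))
})

test_that("canopy traits are drawn within their clip bounds", {
  u1 <- generate_landscape("urban1", seed = 3)
  veg <- u1$cover != "bare"
  expect_true(all(u1$canopy_coverage[veg] >= 5 & u1$canopy_coverage[veg] <= 100))
  expect_true(all(u1$canopy_diameter[veg] >= 1 & u1$canopy_diameter[veg] <= 10))
  expect_true(all(u1$canopy_coverage[!veg] == 0))
})

test_that("the same seed reproduces a landscape exactly", {
  a <- generate_landscape("urban2", seed = 7)
  b <- generate_landscape("urban2", seed = 7)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("detection traps sit one per quarter in host sectors", {
  for (site in c("farm", "urban4")) {
    ls <- place_detection_traps(generate_landscape(site, seed = 1), seed = 1)
    tr <- ls[!is.na(ls$trap_id), ]
    expect_equal(nrow(tr), 4L)
    expect_true(all(tr$cover == "host"))
    quarter <- paste(tr$row %/% 20, tr$col %/% 20)
    expect_equal(sort(unique(quarter)), sort(quarter))
  }
  ls1 <- place_detection_traps(generate_landscape("farm", seed = 5), seed = 5)
  ls2 <- place_detection_traps(generate_landscape("farm", seed = 5), seed = 5)
  expect_identical(ls1$trap_id, ls2$trap_id)
})

test_that("validation traps form pairs at the nominal release distances", {
  ls <- place_validation_traps(homogeneous_landscape())
  tr <- ls[!is.na(ls$trap_id), ]
  expect_equal(nrow(tr), 8L)
  centre <- ls[ls$row == 20 & ls$col == 20, ]
  d <- sqrt((tr$x - centre$x)^2 + (tr$y - centre$y)^2)
  expect_equal(sort(attr(ls, "trap_distance")), rep(c(75, 150, 300, 600), each = 2))
  expect_true(all(abs(sort(d) - sort(attr(ls, "trap_distance"))) <= 12.5))
  expect_true(is.na(centre$trap_id))
})
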