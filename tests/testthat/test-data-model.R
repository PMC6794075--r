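test_that("prior levels and iEVs follow the likelihood-ratio arithmetic", {
  # the four printed iEV pairs and levels, for all seven ratios
  expected <- list(
    list(r = c(6, 0), iev = c(0.875, 0.125), level = 0.75, rule = "ccw"),
    list(r = c(5, 1), iev = c(0.750, 0.250), level = 0.50, rule = "ccw"),
    list(r = c(4, 2), iev = c(0.625, 0.375), level = 0.25, rule = "ccw"),
    list(r = c(3, 3), iev = c(0.500, 0.500), level = 0.00, rule = "tie"),
    list(r = c(2, 4), iev = c(0.375, 0.625), level = 0.25, rule = "cw"),
    list(r = c(1, 5), iev = c(0.250, 0.750), level = 0.50, rule = "cw"),
    list(r = c(0, 6), iev = c(0.125, 0.875), level = 0.75, rule = "cw"))
  for (e in expected) {
    d <- derivePriorLevel(e$r)
    expect_equal(unname(d$iev), e$iev)
    expect_equal(d$level, e$level)
    expect_equal(d$high_prior_rule, e$rule)
  }
})

test_that("prior level derivation is symmetric and rejects bad ratios", {
  for (k in 0:6) {
    expect_equal(derivePriorLevel(c(k, 6 - k))$level,
                 derivePriorLevel(c(6 - k, k))$level)
  }
  expect_error(derivePriorLevel(c(4, 3)), class = "invalidRatioError")
  expect_error(derivePriorLevel(c(-1, 7)), class = "invalidRatioError")
  expect_error(derivePriorLevel(c(6)), class = "invalidRatioError")
})

test_that("epoch rates use half-open windows and are additive", {
  tr <- handTrial(t_precue_on = 1000)
  w <- epochWindows()
  baseline <- w[w$name == "baseline", ]
  # 9 spikes in 300 ms -> 30 Hz
  expect_equal(epochRate(seq(701, 999, length.out = 9), baseline, tr), 30)
  expect_equal(epochRate(numeric(), baseline, tr), 0)
  # half-open: spike exactly at the window end is excluded
  expect_equal(epochRate(c(1000), baseline, tr), 0)
  expect_equal(epochRate(c(999.999), baseline, tr), 1 / 0.3)
  # additivity over disjoint windows covering the same span
  spikes <- runif(50, 700, 1300)
  precue <- w[w$name == "precue", ]
  both <- epochRate(spikes, baseline, tr) + epochRate(spikes, precue, tr)
  expect_equal(both, sum(spikes >= 700 & spikes < 1300) / 0.3)
  # missing anchor event
  tr2 <- tr; tr2$t_precue_on <- NA
  expect_error(epochRate(spikes, baseline, tr2),
               class = "missingEventError")
})

test_that("session validity enforces the trial-record invariants", {
  tr <- handTrial()
  un <- handUnits()
  sp <- data.frame(unit_id = "u1", trial_id = "t1", time_ms = 500)
  expect_s4_class(ReachSession(un, tr, sp), "ReachSession")

  bad <- tr; bad$t_movement_on <- bad$t_go - 5  # movement before go
  expect_error(ReachSession(un, bad, sp), "monotone|rt")
  bad <- tr; bad$rt <- 900; bad$t_movement_on <- bad$t_go + 900
  bad$t_movement_off <- bad$t_movement_on + 300
  expect_error(ReachSession(un, bad, sp), "800")
  bad <- tr; bad$prior_ccw <- 4  # ratio not summing to 6
  expect_error(ReachSession(un, bad, sp), "ratio")
  bad <- tr; bad$reach_direction <- 180  # not precue +/- 90
  expect_error(ReachSession(un, bad, sp), "90")
  bad <- tr; bad$trial_type <- "free_choice"  # instructed_rule != none
  expect_error(ReachSession(un, bad, sp), "free-choice")
  badsp <- data.frame(unit_id = "zzz", trial_id = "t1", time_ms = 500)
  expect_error(ReachSession(un, tr, badsp), "unknown unit_id")
})

test_that("datasets round-trip through CSV exactly", {
  sess <- simulateSession(list(sim = list(n_units_per_area = 2,
                                          n_blocks = 4)), seed = 7)
  dir <- tempfile("ds")
  writeDataset(sess, dir)
  back <- readDataset(dir)
  expect_equal(trialTable(back), trialTable(sess), tolerance = 1e-12)
  expect_equal(unitTable(back), unitTable(sess), tolerance = 1e-12)
  expect_equal(spikeTable(back), spikeTable(sess), tolerance = 1e-12)

  # empty spike table is a valid bundle
  empty <- ReachSession(unitTable(sess), trialTable(sess),
                        spikeTable(sess)[0, ])
  dir2 <- tempfile("ds")
  writeDataset(empty, dir2)
  expect_equal(nrow(spikeTable(readDataset(dir2))), 0)

  expect_error(readDataset(tempfile("nope")),
               class = "schemaValidationError")
})
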