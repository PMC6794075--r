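test_that("directional tuning vectors sum cardinal unit vectors", {
  flat <- directionalTuningVector(c(10, 10, 10, 10))
  expect_equal(flat$magnitude, 0)
  expect_false(flat$defined)
  one <- directionalTuningVector(c(10, 0, 0, 0))
  expect_equal(one$angle, 0)
  expect_equal(one$magnitude, 10)
  mix <- directionalTuningVector(c(8, 4, 2, 4))
  expect_equal(unname(mix$vector), c(6, 0))
  expect_equal(mix$angle, 0)
  diag <- directionalTuningVector(c(5, 5, 0, 0))
  expect_equal(diag$angle, 45)
})

test_that("selectivity test is calibrated and powered", {
  # degenerate all-equal input -> p = 1 by convention
  expect_equal(selectivityTest(rep(3, 24),
                               rep(c(0, 90, 180, 270), 6))$p, 1)
  # insufficient trials flags untestable instead of erroring
  expect_false(selectivityTest(1:4, c(0, 90, 180, 270))$testable)
  withr::with_seed(21, {
    dirs <- rep(c(0, 90, 180, 270), each = 12)
    # type-I: null rejections near alpha
    p_null <- replicate(400, selectivityTest(rnorm(48, 10), dirs)$p)
    rate <- mean(p_null < 0.05)
    expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
    # power: +20 Hz shift in one direction, n = 12 per group
    p_alt <- replicate(100, {
      r <- rnorm(48, 10, 5) + ifelse(dirs == 90, 20, 0)
      selectivityTest(r, dirs)$p
    })
    expect_gt(mean(p_alt < 0.01), 0.95)
  })
})

test_that("trigonometric interpolation is exact at samples and on cos", {
  f_const <- interpolateTuning(rep(2.5, 4))
  expect_equal(f_const(seq(0, 359, by = 7)),
               rep(2.5, length(seq(0, 359, by = 7))))
  f_cos <- interpolateTuning(c(1, 0, -1, 0))
  th <- seq(0, 359.5, by = 0.5)
  expect_equal(f_cos(th), cos(th * pi / 180), tolerance = 1e-12)
  withr::with_seed(3, {
    for (i in 1:20) {
      s <- rnorm(4)
      f <- interpolateTuning(s)
      expect_equal(f(c(0, 90, 180, 270)), s, tolerance = 1e-9)
    }
    # agreement with a direct DFT reconstruction oracle
    s <- rnorm(4)
    co <- fft(s) / 4
    th <- seq(0, 350, by = 10)
    oracle <- Re(co[1]) + 2 * Re(co[2]) * cos(th * pi / 180) +
      2 * -Im(co[2]) * sin(th * pi / 180) +
      Re(co[3]) * cos(2 * th * pi / 180)
    expect_equal(interpolateTuning(s)(th), oracle, tolerance = 1e-9)
  })
})

test_that("motor-goal gating removes untuned and low-rate units", {
  sess <- smallSession()
  g <- smallGating()
  truth <- unitTable(sess)$truth_klass[match(g$unit_id,
                                             unitTable(sess)$unit_id)]
  # untuned units are never gated in
  expect_true(all(!g$gated[truth == "untuned"]))
  # most tuned units pass (high-rate, strongly selective construction)
  expect_gt(mean(g$gated[truth != "untuned"]), 0.7)
  # a tuned unit with ~1 Hz rates fails the 5 Hz gate
  cfgq <- list(sim = list(n_units_per_area = 2, n_sessions = 1,
                          n_blocks = 20, baseline_rate_mean = 0.2,
                          tuning_gain_mean = 0.6,
                          class_mixture = c(UR = 0, DR = 1, untuned = 0)))
  quiet <- simulateSession(cfgq, seed = 31)
  gq <- gateMotorGoalUnits(quiet)
  expect_true(all(!gq$gated))
  expect_true(all(!gq$passes_rate_gate))
  # gating errors without full-prior instructed trials
  tr <- trialTable(sess)
  sub <- tr[tr$prior_level < 0.75, ]
  sp <- spikeTable(sess)
  sess2 <- ReachSession(unitTable(sess), sub,
                        sp[sp$trial_id %in% sub$trial_id, ])
  expect_error(gateMotorGoalUnits(sess2), class = "gatingError")
})

test_that("estimated preferred directions match the ground truth", {
  sess <- smallSession()
  g <- smallGating()
  un <- unitTable(sess)
  m <- merge(g[g$gated, ], un[, c("unit_id", "truth_pd", "truth_klass")])
  expect_true(all(m$pd_max == m$truth_pd))
  # DTV angle close to the discrete PD for gated units
  expect_true(all(angleDistance(m$pd_continuous, m$truth_pd) < 45))
})

test_that("population tuning is aligned, normalized, and graded", {
  sess <- smallSession()
  g <- smallGating()
  un <- unitTable(sess)
  pt <- populationTuning(sess, g)
  # normalization anchor: full-prior response at aligned 0 equals 1
  anchor <- pt[pt$prior_level == 0.75 & pt$aligned_direction == 0, ]
  expect_equal(anchor$mean, 1, tolerance = 0.05)
  # single unit: population curve equals its own normalized curve
  one <- g$unit_id[g$gated][1]
  pt1 <- populationTuning(sess, g, units = one)
  expect_equal(pt1$n_units, rep(1L, nrow(pt1)))
  # DR population at zero prior: lobes at 0 and 180 exceed +/- 90
  dr <- un$unit_id[un$truth_klass == "DR"]
  ptd <- populationTuning(sess, g, units = dr)
  z <- ptd[ptd$prior_level == 0, ]
  lobes <- z$mean[z$aligned_direction %in% c(0, 180)]
  orth <- z$mean[z$aligned_direction %in% c(90, 270)]
  expect_gt(min(lobes), max(orth))
  # graded: UR aligned-0 response monotone in prior level
  ur <- un$unit_id[un$truth_klass == "UR"]
  ptu <- populationTuning(sess, g, units = ur)
  at0 <- ptu[ptu$aligned_direction == 0, ]
  at0 <- at0[order(at0$prior_level), ]
  expect_true(all(diff(at0$mean) > 0))
})
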