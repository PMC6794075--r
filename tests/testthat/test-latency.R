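# hand-built ndInput objects for the arithmetic contracts
makeNdInput <- function(diffArray, time = NULL) {
  if (is.null(time)) time <- seq_len(dim(diffArray)[2]) - 1
  structure(list(time = time, diff = diffArray,
                 unit_ids = paste0("u", seq_len(dim(diffArray)[1])),
                 n_trials = NULL, dropped = character()),
            class = "ndInput")
}

test_that("neural distance is the per-location euclidean norm", {
  # identical trajectories -> nd == 0
  z <- makeNdInput(array(0, c(3, 50, 4)))
  expect_true(all(neuralDistance(z)$nd == 0))
  # one unit with constant difference d -> nd == |d|
  a <- array(0, c(1, 50, 1)); a[1, , 1] <- -2.5
  expect_true(all(neuralDistance(makeNdInput(a))$nd == 2.5))
  # two units -> sqrt(a^2 + b^2)
  b <- array(0, c(2, 50, 1)); b[1, , 1] <- 3; b[2, , 1] <- 4
  expect_true(all(neuralDistance(makeNdInput(b))$nd == 5))
  # invariant to unit order and per-unit sign
  withr::with_seed(81, {
    d <- array(rnorm(5 * 40 * 4), c(5, 40, 4))
    nd1 <- neuralDistance(makeNdInput(d))$nd
    d2 <- d[c(3, 1, 5, 2, 4), , , drop = FALSE]
    d2[2, , ] <- -d2[2, , ]
    expect_equal(neuralDistance(makeNdInput(d2))$nd, nd1)
  })
})

test_that("latency estimates find inflections with earliest-tie rule", {
  t <- 0:600
  # logistic with inflection at 150 ms
  nd <- 5 / (1 + exp(-(t - 150) / 25))
  le <- latencyEstimates(nd, t, window = c(0, 600), threshold = 0.01)
  expect_lt(abs(le$mvt - 150), 2)
  expect_gte(le$pt, le$mvt)
  # linear ramp: maximal velocity everywhere -> earliest bin wins
  ramp <- latencyEstimates(0.01 * t, t, window = c(50, 400))
  expect_equal(ramp$mvt, 50)
  # flat trajectory -> no latency
  flat <- latencyEstimates(rep(1, 601), t)
  expect_false(flat$found)
  # latencies are scale-free; nd scale only affects the velocity
  le2 <- latencyEstimates(10 * nd, t, window = c(0, 600),
                          threshold = 0.01 * 10)
  expect_equal(le2$mvt, le$mvt)
})

test_that("bootstrap CIs degenerate correctly and cover the estimate", {
  # identical units: zero-width CI
  a <- array(0, c(6, 200, 2))
  for (i in 1:6) a[i, , ] <- 3 / (1 + exp(-((0:199) - 80) / 15))
  bi <- makeNdInput(a)
  bs <- bootstrapND(bi, nBoot = 60, seed = 3, window = c(0, 199),
                    threshold = 1e-4)
  expect_equal(bs$mvt_ci[1], bs$mvt_ci[2])
  expect_equal(bs$mvt_ci[1], bs$estimate$mvt)
  # heterogeneous units: CI covers the point estimate
  withr::with_seed(82, {
    for (i in 1:6) a[i, , ] <- (2 + rnorm(1, 0, 0.3)) /
      (1 + exp(-((0:199) - 80 - rnorm(1, 0, 10)) / 15))
    bs2 <- bootstrapND(makeNdInput(a), nBoot = 120, seed = 4,
                       window = c(0, 199), threshold = 1e-4)
    expect_gte(bs2$estimate$mvt, bs2$mvt_ci[1])
    expect_lte(bs2$estimate$mvt, bs2$mvt_ci[2])
  })
})

test_that("the permutation test is exact under exchangeability", {
  # A == B: observed difference 0, p = 1
  a <- array(0, c(4, 150, 2))
  for (i in 1:4) a[i, , ] <- 2 / (1 + exp(-((0:149) - 60) / 10))
  pt <- permutationAreaTest(makeNdInput(a), makeNdInput(a), nPerm = 200,
                            seed = 5, window = c(0, 149),
                            threshold = 1e-4)
  expect_equal(pt$mvt_diff, 0)
  expect_equal(pt$p_mvt, 1)
  expect_warning(
    permutationAreaTest(makeNdInput(a), makeNdInput(a), nPerm = 50,
                        seed = 5, window = c(0, 149)),
    "coarse")
})

test_that("an injected latency offset is recovered from simulated data", {
  # two small same-session populations with a 50 ms class offset
  cfg <- list(sim = list(n_units_per_area = 8, n_sessions = 1,
                         n_blocks = 60,
                         class_mixture = c(UR = 0.5, DR = 0.5,
                                           untuned = 0),
                         selection_latency = list(PMd_DR = 80,
                                                  PMd_UR = 130,
                                                  PRR_DR = 80,
                                                  PRR_UR = 130),
                         selection_latency_jitter_sd = 5))
  sess <- simulateSession(cfg, seed = 210)
  g <- gateMotorGoalUnits(sess)
  un <- unitTable(sess)
  dr <- intersect(g$unit_id[g$gated], un$unit_id[un$truth_klass == "DR"])
  ur <- intersect(g$unit_id[g$gated], un$unit_id[un$truth_klass == "UR"])
  nd_dr <- neuralDistanceInput(sess, g, units = dr)
  nd_ur <- neuralDistanceInput(sess, g, units = ur)
  le_dr <- latencyEstimates(neuralDistance(nd_dr))
  le_ur <- latencyEstimates(neuralDistance(nd_ur))
  expect_true(le_dr$found && le_ur$found)
  expect_lt(abs((le_ur$mvt - le_dr$mvt) - 50), 20)
  pt <- permutationAreaTest(nd_dr, nd_ur, nPerm = 300, seed = 6)
  expect_lt(pt$p_mvt, 0.05)
})
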