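# direct construction of per-trial normalized rates with known slopes
makeModTrials <- function(slope_pd, slope_od, n_per = 30, noise = 0.25,
                          base = 1) {
  levs <- rep(c(0.25, 0.5, 0.75), each = n_per)
  d <- rbind(
    data.frame(role = "PD_max", lev = levs,
               y = base + slope_pd * levs + rnorm(length(levs), 0, noise)),
    data.frame(role = "OD", lev = levs,
               y = base + slope_od * levs + rnorm(length(levs), 0, noise)))
  d
}

test_that("unit modulation fits recover injected slopes and classes", {
  withr::with_seed(51, {
    d <- makeModTrials(2, 0)
    r <- fitUnitModulation(d$y, d$lev, d$role)
    expect_equal(r$slope_pd, 2, tolerance = 0.25)
    expect_lt(abs(r$slope_od), 0.3)
    expect_equal(r$klass, "UR")
    expect_gt(r$angle, pi / 4)

    d <- makeModTrials(0, -2)
    r <- fitUnitModulation(d$y, d$lev, d$role)
    expect_equal(r$slope_od, -2, tolerance = 0.25)
    expect_equal(r$klass, "DR")
    expect_lt(r$angle, pi / 4)

    # null units stay unclassified at roughly the nominal error rate
    klasses <- replicate(150, {
      d <- makeModTrials(0, 0)
      fitUnitModulation(d$y, d$lev, d$role)$klass
    })
    expect_lt(mean(klasses != "none"), 0.15)
  })
})

test_that("classification is invariant to uniform rate rescaling", {
  withr::with_seed(52, {
    d <- makeModTrials(1.5, -0.2)
    r1 <- fitUnitModulation(d$y, d$lev, d$role)
    r2 <- fitUnitModulation(10 * d$y, d$lev, d$role)
    expect_equal(r2$klass, r1$klass)
    expect_equal(r2$p_pd, r1$p_pd, tolerance = 1e-9)
    expect_equal(r2$slope_pd, 10 * r1$slope_pd, tolerance = 1e-9)
  })
})

test_that("degenerate modulation inputs are flagged unfittable", {
  r <- fitUnitModulation(rnorm(10), rep(0.5, 10), rep("PD_max", 10))
  expect_false(r$fittable)
  expect_equal(r$klass, "none")
})

test_that("classifyUnits recovers ground-truth classes on a session", {
  sess <- smallSession()
  g <- smallGating()
  cl <- classifyUnits(sess, g, seed = 5,
                      config = list(analysis = list(dip_n_boot = 500)))
  truth <- unitTable(sess)$truth_klass[match(cl$unit_id,
                                             unitTable(sess)$unit_id)]
  decided <- cl$klass != "none"
  expect_gt(mean(cl$klass[decided] == truth[decided]), 0.9)
  # angles of UR units sit near pi/2, DR units near 0
  expect_true(all(cl$angle[cl$klass == "UR"] > pi / 4, na.rm = TRUE))
  expect_true(all(cl$angle[cl$klass == "DR"] < pi / 4, na.rm = TRUE))
})

test_that("population modulation separates the roles by class", {
  sess <- smallSession()
  g <- smallGating()
  un <- unitTable(sess)
  ur <- un$unit_id[un$truth_klass == "UR"]
  dr <- un$unit_id[un$truth_klass == "DR"]
  pm_ur <- populationModulationTest(sess, g, units = ur)
  s <- pm_ur$slopes
  expect_gt(s$mean_slope[s$role == "PD_max"], 0)
  expect_lt(s$p[s$role == "PD_max"], 0.01)
  expect_gt(s$p[s$role == "Orth"], 0.05)   # no orthogonal modulation
  pm_dr <- populationModulationTest(sess, g, units = dr)
  sd_ <- pm_dr$slopes
  expect_lt(sd_$mean_slope[sd_$role == "OD"], 0)
  expect_lt(sd_$p[sd_$role == "OD"], 0.01)
  expect_gt(sd_$p[sd_$role == "Orth"], 0.05)
  # posthoc output covers successive level pairs with corrected p
  ph <- pm_ur$posthoc
  expect_true(all(ph$p_bonf >= ph$p_raw - 1e-12))
  expect_true(all(ph$level_b > ph$level_a))
})

test_that("permuted prior labels yield null modulation", {
  withr::with_seed(53, {
    sess <- smallSession()
    g <- smallGating()
    tr0 <- trialTable(sess)
    # average over several independent label permutations: one draw is
    # shared by all units, so false positives are correlated within it
    rates <- replicate(6, {
      tr <- tr0
      for (ss in unique(tr$session_id)) {
        idx <- which(tr$session_id == ss)
        sh <- sample(idx)
        cols <- c("prior_ccw", "prior_cw", "prior_level",
                  "high_prior_rule")
        tr[idx, cols] <- tr[sh, cols]
      }
      sess2 <- ReachSession(unitTable(sess), tr, spikeTable(sess))
      md <- priorreach:::modulationData(sess2, g)
      cl <- do.call(rbind, lapply(split(md, md$unit_id), function(d)
        fitUnitModulation(d$norm_rate, d$prior_level, d$role)))
      mean(cl$klass != "none")
    })
    expect_lt(mean(rates), 0.2)
  })
})
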