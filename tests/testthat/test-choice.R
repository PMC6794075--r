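test_that("choice trials are sorted into prior/reach roles correctly", {
  tr <- handTrial()
  tr$trial_type <- "free_choice"; tr$instructed_rule <- "none"
  # precue 0, high prior ccw -> prior goal 90; unit PD_max = 90
  tr$chosen_rule <- "ccw"; tr$reach_direction <- 90
  s <- sortChoiceTrials(90, tr)
  expect_equal(s$prior_role, "Prior-in")
  expect_equal(s$reach_role, "Reach-in")
  # higher prior at OD, reach to PD_max -> against combination
  tr2 <- tr; tr2$prior_ccw <- 1; tr2$prior_cw <- 5
  tr2$high_prior_rule <- "cw"   # prior goal 270 = OD of this unit
  s2 <- sortChoiceTrials(90, tr2)
  expect_equal(s2$prior_role, "Prior-out")
  expect_equal(s2$reach_role, "Reach-in")
  # goals orthogonal to the PD axis -> Orth, excluded from in/out
  s3 <- sortChoiceTrials(0, tr)
  expect_equal(s3$prior_role, "Orth")
  # zero-prior trials carry a neutral prior label
  tr4 <- tr; tr4$prior_ccw <- 3; tr4$prior_cw <- 3
  tr4$prior_level <- 0; tr4$high_prior_rule <- "tie"
  expect_equal(sortChoiceTrials(90, tr4)$prior_role, "neutral")
})

test_that("auroc matches the exhaustive pair-counting oracle", {
  pairCount <- function(a, b) {
    s <- 0
    for (x in a) for (y in b) s <- s + (x > y) + 0.5 * (x == y)
    s / (length(a) * length(b))
  }
  expect_equal(auroc(c(5, 6, 7), c(1, 2, 3), minN = 3)$auc, 1)
  expect_equal(auroc(1:10, 1:10, minN = 5)$auc, 0.5)
  withr::with_seed(91, {
    for (rep in 1:25) {
      na <- sample(5:50, 1); nb <- sample(5:50, 1)
      a <- sample(0:8, na, replace = TRUE)   # heavy ties
      b <- sample(0:8, nb, replace = TRUE) + rnorm(nb, 0, 0.3)
      expect_equal(auroc(a, b)$auc, pairCount(a, b), tolerance = 1e-12)
      # complement symmetry
      expect_equal(auroc(a, b)$auc + auroc(b, a)$auc, 1)
    }
  })
  expect_false(auroc(1:3, 1:10)$ok)  # below the trial minimum
})

test_that("co-encoding populations predict priors but not choices", {
  sess <- smallSession()
  g <- smallGating()
  suite <- choiceRocSuite(sess, g,
                          config = list(analysis = list(roc_min_trials = 4)))
  sm <- suite$summary
  between <- sm$mean_auc[sm$comparison == "between_prior"]
  within <- sm$mean_auc[grepl("within", sm$comparison)]
  expect_gt(between, 0.6)
  expect_true(all(abs(within - 0.5) < 0.12))
  # premature-commitment variant: planning activity betrays the choice
  sessc <- simulateSession(list(sim = list(n_units_per_area = 6,
                                           n_blocks = 30,
                                           commitment_gain = 1)),
                           seed = 101)
  gc_ <- gateMotorGoalUnits(sessc)
  suitec <- choiceRocSuite(sessc, gc_,
                           config = list(analysis = list(roc_min_trials = 4)))
  smc <- suitec$summary
  withinc <- smc$mean_auc[grepl("within", smc$comparison)]
  expect_gt(max(withinc), 0.6)
})

test_that("shuffled choice labels drive within-condition AUC to chance", {
  withr::with_seed(92, {
    sess <- smallSession()
    g <- smallGating()
    tr <- trialTable(sess)
    fc <- which(tr$trial_type == "free_choice" & tr$outcome == "correct")
    # shuffle the executed choice among free-choice trials per session
    for (ss in unique(tr$session_id)) {
      idx <- fc[tr$session_id[fc] == ss]
      sh <- sample(idx)
      cols <- c("chosen_rule", "reach_direction", "congruency")
      tr[idx, cols] <- tr[sh, cols]
    }
    # keep reach_direction consistent with precue (swap may break it)
    ok <- is.na(tr$reach_direction) |
      angleDistance(tr$reach_direction, tr$precue_location) == 90
    tr <- tr[ok, ]
    sp <- spikeTable(sess)
    sess2 <- ReachSession(unitTable(sess), tr,
                          sp[sp$trial_id %in% tr$trial_id, ])
    suite <- choiceRocSuite(sess2, g,
                            config = list(analysis =
                                            list(roc_min_trials = 4)))
    sm <- suite$summary
    within <- sm$mean_auc[grepl("within", sm$comparison)]
    expect_true(all(abs(within - 0.5) < 0.12))
  })
})

test_that("signal correlations respect their algebraic contracts", {
  sess <- smallSession()
  g <- smallGating()
  sc <- signalCorrelations(sess, g)
  expect_true(all(sc$pairs$r >= -1 - 1e-9 & sc$pairs$r <= 1 + 1e-9))
  expect_true(all(sc$pairs$pd_distance %in% c(0, 90, 180)))
  # a duplicated unit gives r = 1 at every level
  un <- unitTable(sess); sp <- spikeTable(sess)
  gu <- g$unit_id[g$gated][1]
  dup_unit <- un[un$unit_id == gu, ]; dup_unit$unit_id <- "dup"
  dup_sp <- sp[sp$unit_id == gu, ]; dup_sp$unit_id <- "dup"
  sess2 <- ReachSession(rbind(un, dup_unit), trialTable(sess),
                        rbind(sp, dup_sp))
  g2 <- rbind(g, transform(g[g$unit_id == gu, ], unit_id = "dup"))
  sc2 <- signalCorrelations(sess2, g2)
  dup_rows <- sc2$pairs[sc2$pairs$unit_a == gu & sc2$pairs$unit_b == "dup" |
                          sc2$pairs$unit_a == "dup" &
                          sc2$pairs$unit_b == gu, ]
  expect_true(nrow(dup_rows) > 0)
  expect_true(all(abs(dup_rows$r - 1) < 1e-9))
  # opposite-PD anti-correlation strengthens with prior: co-planning of
  # both goals turns into competition as one option gains priority
  dr <- unitTable(sess)$unit_id[unitTable(sess)$truth_klass == "DR"]
  opp <- sc$pairs[sc$pairs$pd_distance == 180 &
                    sc$pairs$unit_a %in% dr & sc$pairs$unit_b %in% dr, ]
  if (nrow(opp) >= 4) {
    z0 <- mean(opp$r[opp$prior_level == 0])
    z3 <- mean(opp$r[opp$prior_level == 0.75])
    expect_lt(z3, z0)
  }
  # the prior-trend model for the 180-degree bin sees the decline
  tr180 <- sc$trend180$coefficients
  sl <- tr180[tr180$term == "prior_level", ]
  expect_lt(sl$estimate, 0)
  expect_lt(sl$p, 0.01)
})
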