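cfgSmall <- function(...) {
  validateConfig(list(sim = modifyList(
    list(n_units_per_area = 2, n_sessions = 1, n_blocks = 8), list(...))))
}

test_that("trial plans respect the block design", {
  cfg <- cfgSmall(n_blocks = 14)
  tr <- planTrials(cfg, seed = 1)
  expect_equal(nrow(tr), 14 * 8)
  byblock <- split(tr, tr$block)
  for (b in byblock) {
    expect_equal(nrow(b), 8)
    expect_equal(sum(b$trial_type == "free_choice"), 2)
    expect_equal(sum(b$trial_type == "instructed"), 6)
    expect_equal(length(unique(b$prior_ccw)), 1)  # prior constant in block
  }
  # full-prior blocks instruct only the high-prior rule
  full <- tr[tr$prior_level == 0.75 & tr$trial_type == "instructed", ]
  expect_true(all(full$instructed_rule == full$high_prior_rule))
  # free-choice rewards are 1.5 or 0.5 units
  expect_true(all(tr$reward_if_correct[tr$trial_type == "free_choice"]
                  %in% c(0.5, 1.5)))
  # same seed reproduces the identical plan
  expect_identical(tr, planTrials(cfg, seed = 1))
  expect_false(identical(tr, planTrials(cfg, seed = 2)))
})

test_that("behavior generation follows the configured choice and RT laws", {
  # null bias: P(follow) ~ 0.5 at every level
  cfg0 <- cfgSmall(n_blocks = 400,
                   behavior = list(choice_bias_slope = 0,
                                   rt_congruency_effect = 0))
  tr <- generateBehavior(planTrials(cfg0, 1), cfg0, 2)
  fc <- tr[tr$trial_type == "free_choice" & tr$prior_level > 0, ]
  p <- mean(fc$congruency == "follow")
  ci <- 3 * sqrt(0.25 / nrow(fc))
  expect_lt(abs(p - 0.5), ci)
  # null RT effect: follow and against means equal within CI
  dfollow <- fc$rt[fc$congruency == "follow"]
  dagainst <- fc$rt[fc$congruency == "against"]
  expect_gt(t.test(dfollow, dagainst)$p.value, 0.001)

  # strong bias at level 0.75 matches the configured logistic
  cfg1 <- cfgSmall(n_blocks = 400,
                   behavior = list(choice_bias_slope = 4))
  tr1 <- generateBehavior(planTrials(cfg1, 1), cfg1, 2)
  fc1 <- tr1[tr1$trial_type == "free_choice" & tr1$prior_level == 0.75, ]
  target <- plogis(4 * 0.75)
  expect_lt(abs(mean(fc1$congruency == "follow") - target),
            3 * sqrt(target * (1 - target) / nrow(fc1)) + 0.01)
  # RTs respect the 800 ms limit
  expect_true(all(tr1$rt < 800))
  expect_equal(tr1$t_movement_on - tr1$t_go, tr1$rt)
})

test_that("rate profiles encode the UR/DR phenomenology", {
  unit <- data.frame(
    unit_id = "u", truth_klass = "DR", truth_pd = 90,
    truth_baseline_rate = 10, truth_tuning_gain = 20,
    truth_tuning_width = 2, truth_prior_slope = 1.4,
    truth_selection_latency = 100, stringsAsFactors = FALSE)
  mkTrial <- function(precue, ccw, cw, reach) {
    t <- handTrial()
    t$precue_location <- precue
    t$prior_ccw <- ccw; t$prior_cw <- cw
    t$prior_level <- abs(ccw - cw) / 8
    t$high_prior_rule <- if (ccw > cw) "ccw" else if (cw > ccw) "cw"
      else "tie"
    t$reach_direction <- reach
    t
  }
  t_plan <- function(t) t$t_rulecue_on - 150  # mid-planning

  # DR, zero prior, goals at PD/OD: both lobes full, rate above baseline
  tz <- mkTrial(0, 3, 3, 90)  # goals 90 (ccw) and 270 (cw)
  r_pd_od <- rateProfile(unit, tz, t_plan(tz))
  expect_equal(r_pd_od, 10 + 20)  # PD lobe 1, OD lobe 0

  # symmetric construction: zero-prior rate identical whichever goal pair
  tz2 <- mkTrial(180, 3, 3, 90)
  expect_equal(rateProfile(unit, tz2, t_plan(tz2)), r_pd_od)

  # orthogonal goals evoke baseline only, at every prior level
  for (cc in list(c(3, 3), c(6, 0), c(1, 5))) {
    to <- mkTrial(90, cc[1], cc[2], 0)  # goals 180/0, orth to pd 90
    expect_equal(rateProfile(unit, to, t_plan(to)), 10)
  }

  # full prior away from PD: response drops below the orthogonal level
  ta <- mkTrial(0, 0, 6, 270)  # high prior cw -> goal 270 (OD)
  r_away <- rateProfile(unit, ta, t_plan(ta))
  expect_lt(r_away, 10)
  expect_equal(r_away, 10 + 20 * (1 - 1.4 * 0.75))

  # UR: no direction preference at zero prior; graded gain toward PD
  ur <- unit; ur$truth_klass <- "UR"; ur$truth_prior_slope <- 1
  expect_equal(rateProfile(ur, tz, t_plan(tz)), 10)
  tp <- mkTrial(0, 6, 0, 90)  # high prior ccw -> goal 90 = PD
  expect_equal(rateProfile(ur, tp, t_plan(tp)), 10 + 20 * 0.75)
  # after the selection transition, movement coding of the executed goal
  expect_equal(rateProfile(ur, tp, tp$t_rulecue_on + 150), 10 + 20)
  # before the transition (latency 100 ms) planning coding persists
  expect_equal(rateProfile(ur, tp, tp$t_rulecue_on + 50), 10 + 20 * 0.75)
})

test_that("Poisson spike generation matches configured rates", {
  cfg <- cfgSmall(n_blocks = 60, class_mixture = c(UR = 0, DR = 0,
                                                   untuned = 1))
  units <- sampleUnits(cfg, 1)
  trials <- generateBehavior(planTrials(cfg, 2), cfg, 3)
  spikes <- generateSpikes(units, trials, cfg, 4)
  # total counts within 3 sigma of the Poisson expectation per unit
  tot_s <- sum(trials$t_movement_off + 300) / 1000
  for (i in seq_len(nrow(units))) {
    lambda <- units$truth_baseline_rate[i] * tot_s
    n <- sum(spikes$unit_id == units$unit_id[i])
    expect_lt(abs(n - lambda), 3 * sqrt(lambda) + 1)
  }
  # reproducibility and seed sensitivity
  expect_identical(spikes, generateSpikes(units, trials, cfg, 4))
  expect_false(identical(spikes, generateSpikes(units, trials, cfg, 5)))
  # zero-rate unit emits no spikes
  u0 <- units[1, ]; u0$truth_baseline_rate <- 1e-9
  expect_equal(nrow(generateSpikes(u0, trials, cfg, 6)), 0)
})

test_that("one root seed spawns reproducible independent stage streams", {
  s1 <- simulateSession(list(sim = list(n_units_per_area = 2,
                                        n_blocks = 4)), seed = 9)
  s2 <- simulateSession(list(sim = list(n_units_per_area = 2,
                                        n_blocks = 4)), seed = 9)
  expect_identical(spikeTable(s1), spikeTable(s2))
  expect_identical(trialTable(s1), trialTable(s2))
  expect_true(childSeed(9, "spikes") != childSeed(9, "trials"))
  expect_true(childSeed(9, "spikes") != childSeed(10, "spikes"))
})
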