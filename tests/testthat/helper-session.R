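# Shared small synthetic sessions, built once per test run.

.session_cache <- new.env(parent = emptyenv())

smallSession <- function() {
  if (is.null(.session_cache$small)) {
    .session_cache$small <- simulateSession(
      list(sim = list(n_units_per_area = 6, n_blocks = 30)), seed = 101)
  }
  .session_cache$small
}

smallGating <- function() {
  if (is.null(.session_cache$gating)) {
    .session_cache$gating <- gateMotorGoalUnits(smallSession())
  }
  .session_cache$gating
}

# a minimal hand-built valid trial row (for epoch/window tests)
handTrial <- function(t_precue_on = 1000, rt = 350) {
  t_rule <- t_precue_on + 500 + 900
  data.frame(
    trial_id = "t1", session_id = "s", subject_id = "M1",
    precue_location = 0, prior_ccw = 5, prior_cw = 1, prior_level = 0.5,
    trial_type = "instructed", instructed_rule = "ccw",
    chosen_rule = "none", reach_direction = 90, congruency = "follow",
    rt = rt, outcome = "correct",
    t_fixation_on = 0, t_precue_on = t_precue_on,
    t_precue_off = t_precue_on + 500, t_rulecue_on = t_rule,
    t_go = t_rule, t_movement_on = t_rule + rt,
    t_movement_off = t_rule + rt + 300,
    stringsAsFactors = FALSE)
}

handUnits <- function(n = 1, area = "PMd") {
  data.frame(unit_id = paste0("u", seq_len(n)), session_id = "s",
             subject_id = "M1", area = area, stringsAsFactors = FALSE)
}
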