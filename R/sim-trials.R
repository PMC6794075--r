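#' Plan the trial skeletons of synthetic sessions
#'
#' Builds the block design of the task: priors are drawn per block (each of
#' the seven likelihood ratios appears equally often per session, order
#' shuffled) and held constant within blocks of eight successful trials,
#' two free-choice and six instructed at random positions. Pre-cue
#' locations are drawn per trial from the four cardinal directions.
#' Instructed rules are drawn with probability proportional to the block's
#' likelihood ratio (a 6:0 block always instructs the high-prior rule).
#' Free-choice reward magnitude is pre-drawn as 1.5 or 0.5 units with equal
#' probability (instructed trials are worth 1 unit). Pre-response event
#' times are drawn from the task's timing ranges; response-dependent events
#' (movement onset/offset) are left NA for [generateBehavior()].
#'
#' @param config validated configuration.
#' @param seed integer seed.
#' @return data.frame of trial skeletons (one row per trial).
#' @export
planTrials <- function(config, seed) {
  cfg <- validateConfig(config)
  s <- cfg$sim
  tm <- s$timing
  ratios <- priorRatioTable()
  withSeed(seed, {
    sessions <- lapply(seq_len(s$n_sessions), function(sess) {
      n_blocks <- s$n_blocks
      # balanced, shuffled assignment of the 7 ratios to blocks
      block_ratio <- sample(rep(seq_len(nrow(ratios)),
                                length.out = n_blocks))
      per_block <- lapply(seq_len(n_blocks), function(b) {
        r <- ratios[block_ratio[b], ]
        free_pos <- sample(8L, 2L)
        is_free <- seq_len(8L) %in% free_pos
        instructed_rule <- ifelse(
          is_free, "none",
          ifelse(runif(8L) < r$ccw / 6, "ccw", "cw"))
        data.frame(
          block = b,
          precue_location = sample(CARDINAL_DIRECTIONS, 8L, replace = TRUE),
          prior_ccw = r$ccw, prior_cw = r$cw, prior_level = r$level,
          high_prior_rule = r$high_prior_rule,
          trial_type = ifelse(is_free, "free_choice", "instructed"),
          instructed_rule = instructed_rule,
          reward_if_correct = ifelse(is_free, sample(c(1.5, 0.5), 8L,
                                                     replace = TRUE), 1),
          stringsAsFactors = FALSE
        )
      })
      tr <- do.call(rbind, per_block)
      n <- nrow(tr)
      t_fix <- rep(0, n)
      t_precue_on <- t_fix + runif(n, tm$fixation_min, tm$fixation_max)
      t_precue_off <- t_precue_on + tm$precue_dur
      t_rulecue_on <- t_precue_off + runif(n, tm$memory_min, tm$memory_max)
      tr <- cbind(
        data.frame(trial_id = sprintf("s%d_t%04d", sess, seq_len(n)),
                   session_id = paste0("sess", sess),
                   subject_id = paste0("M", (sess - 1L) %% 2L + 1L),
                   stringsAsFactors = FALSE),
        tr,
        data.frame(t_fixation_on = t_fix, t_precue_on = t_precue_on,
                   t_precue_off = t_precue_off, t_rulecue_on = t_rulecue_on,
                   t_go = t_rulecue_on, t_movement_on = NA_real_,
                   t_movement_off = NA_real_)
      )
      tr
    })
    out <- do.call(rbind, sessions)
    out$chosen_rule <- NA_character_
    out$reach_direction <- NA_real_
    out$congruency <- NA_character_
    out$rt <- NA_real_
    out$outcome <- NA_character_
    rownames(out) <- NULL
    out
  })
}

# Reach goal direction for a rule given the pre-cue location:
# ccw rotates the pre-cue +90 deg, cw rotates -90 deg.
ruleToDirection <- function(rule, precueLocation) {
  wrapAngle(precueLocation + ifelse(rule == "ccw", 90, -90))
}

# Ensure the high_prior_rule convenience column exists (derivable from
# the prior ratio; generator output carries it, external CSVs may not).
ensureHighPriorRule <- function(trials) {
  if (!"high_prior_rule" %in% names(trials)) {
    trials$high_prior_rule <- ifelse(
      trials$prior_ccw > trials$prior_cw, "ccw",
      ifelse(trials$prior_cw > trials$prior_ccw, "cw", "tie"))
  }
  trials
}

# follow/against congruency of an executed rule; in the zero-prior
# condition cw counts as follow by convention.
congruencyOf <- function(rule, highPriorRule) {
  ifelse(highPriorRule == "tie",
         ifelse(rule == "cw", "follow", "against"),
         ifelse(rule == highPriorRule, "follow", "against"))
}
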