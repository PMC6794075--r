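#' Generate behavior for planned trials
#'
#' Completes trial skeletons with choices, errors, reaction times and the
#' response-dependent event times. Free-choice trials select the high-prior
#' rule with logistic probability `plogis(choice_bias_slope * prior_level)`
#' (exactly 1/2 in the zero-prior condition, where cw is then arbitrarily
#' booked as follow). Instructed trials err with probability
#' `error_base + error_congruency_slope * prior_level` when the instruction
#' points against the prior and `error_base * (1 - prior_level)` when it
#' follows it; an error is executed as a reach to the other goal.
#' Reaction times are log-normal around `rt_base` shifted by
#' `+/- rt_congruency_effect * prior_level` (slower against, faster
#' follow), truncated to the task's 800 ms response limit.
#'
#' @param trials trial skeletons from [planTrials()].
#' @param config validated configuration (its `sim$behavior` block is
#'   used).
#' @param seed integer seed.
#' @return the completed trials data.frame.
#' @export
generateBehavior <- function(trials, config, seed) {
  cfg <- validateConfig(config)
  p <- cfg$sim$behavior
  tm <- cfg$sim$timing
  withSeed(seed, {
    n <- nrow(trials)
    lev <- trials$prior_level
    high <- trials$high_prior_rule
    free <- trials$trial_type == "free_choice"

    executed <- character(n)
    outcome <- rep("correct", n)

    # free-choice: logistic bias toward the high-prior rule
    p_follow <- plogis(p$choice_bias_slope * lev)
    u <- runif(n)
    other <- function(rule) ifelse(rule == "ccw", "cw", "ccw")
    fc_high <- ifelse(high == "tie",
                      ifelse(runif(n) < 0.5, "cw", "ccw"), high)
    executed[free] <- ifelse(u[free] < p_follow[free],
                             fc_high[free], other(fc_high[free]))

    # instructed: congruency-dependent error rate
    ins <- !free
    cong_ins <- congruencyOf(trials$instructed_rule, high)
    p_err <- ifelse(cong_ins == "against",
                    pmin(1, p$error_base + p$error_congruency_slope * lev),
                    pmax(0, p$error_base * (1 - lev)))
    err <- ins & runif(n) < p_err
    executed[ins] <- trials$instructed_rule[ins]
    executed[err] <- other(trials$instructed_rule[err])
    outcome[err] <- "error"

    # congruency: by the instruction on instructed trials (so error rates
    # split follow/against instructions), by the choice on free trials
    cong <- ifelse(ins, cong_ins, congruencyOf(executed, high))
    rt_mean <- p$rt_base +
      ifelse(cong == "follow", -1, 1) * p$rt_congruency_effect * lev
    rt <- rlnorm(n, meanlog = log(rt_mean), sdlog = p$rt_noise_sd)
    rt <- pmin(pmax(rt, 150), 799)

    trials$chosen_rule <- ifelse(free, executed, "none")
    trials$reach_direction <- ruleToDirection(executed,
                                              trials$precue_location)
    trials$congruency <- cong
    trials$rt <- rt
    trials$outcome <- outcome
    trials$reward <- ifelse(outcome == "correct",
                            trials$reward_if_correct, 0)
    trials$t_movement_on <- trials$t_go + rt
    trials$t_movement_off <- trials$t_movement_on + tm$movement_dur
    trials
  })
}
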