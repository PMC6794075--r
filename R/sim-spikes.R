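#' Instantaneous firing rate of a synthetic unit in one trial
#'
#' Encodes the two-class phenomenology of prior-modulated motor-goal
#' planning. Before pre-cue onset the unit fires at baseline. From pre-cue
#' onset until its selection transition (rule-cue onset + the unit's
#' selection latency) the planning profile applies:
#' \itemize{
#'   \item DR units carry truncated von-Mises lobes at both potential
#'     goals; the lobe of the low-prior goal is scaled by
#'     `1 - prior_slope * prior_level` (both lobes full at zero prior), so
#'     activity falls with prior pointing away from the preferred
#'     direction.
#'   \item UR units carry a single lobe at the high-prior goal with gain
#'     `prior_slope * prior_level` and no lobe in the zero-prior
#'     condition, so activity grows with prior toward the preferred
#'     direction and UR units are untuned at zero prior.
#'   \item Goals orthogonal to the unit's PD axis evoke no modulation
#'     (the lobes vanish at 90 degrees).
#' }
#' A positive `commitment_gain` (premature-commitment variant, default 0)
#' adds a lobe toward the to-be-chosen goal during planning of free-choice
#' trials. After the selection transition the unit encodes the executed
#' goal only (baseline + lobe at the reach direction) until movement
#' offset, then returns to baseline.
#'
#' @param unit one-row data.frame from [sampleUnits()] (`truth_*` columns).
#' @param trial one-row completed trial data.frame.
#' @param t numeric vector of times (ms from trial start).
#' @param commitmentGain optional premature-commitment lobe gain
#'   (fraction of tuning gain).
#' @return numeric vector of rates in Hz, same length as `t`.
#' @export
rateProfile <- function(unit, trial, t, commitmentGain = 0) {
  rateProfileMulti(unit,
                   trial[rep(1L, length(t)), , drop = FALSE],
                   t, commitmentGain)
}

# Vectorized core: `trials` has one row per element of `t`.
rateProfileMulti <- function(unit, trials, t, commitmentGain = 0) {
  b <- unit$truth_baseline_rate
  g <- unit$truth_tuning_gain
  kappa <- unit$truth_tuning_width
  pd <- unit$truth_pd
  slope <- unit$truth_prior_slope
  klass <- unit$truth_klass
  lat <- unit$truth_selection_latency

  rate <- rep(b, length(t))
  g_ccw <- ruleToDirection("ccw", trials$precue_location)
  g_cw <- ruleToDirection("cw", trials$precue_location)
  lev <- trials$prior_level
  high <- trials$high_prior_rule

  t_sel <- trials$t_rulecue_on + lat
  in_plan <- t >= trials$t_precue_on & t < t_sel
  in_move <- t >= t_sel & t < trials$t_movement_off

  if (g > 0) {
    lobe_ccw <- vonMisesLobe(g_ccw - pd, kappa)
    lobe_cw <- vonMisesLobe(g_cw - pd, kappa)
    if (klass == "DR") {
      # the disregarded (low-prior) goal's lobe is suppressed linearly in
      # prior level; with slope > 4/3 the full-prior response dips below
      # baseline (rates are rectified at zero below)
      w_ccw <- ifelse(high == "cw", 1 - slope * lev, 1)
      w_cw <- ifelse(high == "ccw", 1 - slope * lev, 1)
      plan_extra <- g * (w_ccw * lobe_ccw + w_cw * lobe_cw)
    } else if (klass == "UR") {
      lobe_high <- ifelse(high == "ccw", lobe_ccw,
                          ifelse(high == "cw", lobe_cw, 0))
      plan_extra <- g * slope * lev * lobe_high
    } else {
      plan_extra <- 0
    }
    if (commitmentGain > 0) {
      free <- trials$trial_type == "free_choice"
      lobe_reach <- vonMisesLobe(trials$reach_direction - pd, kappa)
      plan_extra <- plan_extra + ifelse(free, commitmentGain * g *
                                          lobe_reach, 0)
    }
    rate <- rate + ifelse(in_plan, plan_extra, 0)
    rate <- rate + ifelse(in_move,
                          g * vonMisesLobe(trials$reach_direction - pd,
                                           kappa),
                          0)
  }
  if (any(!is.finite(rate)))
    prStop("rateGenerationError", "non-finite rate generated for unit %s",
           unit$unit_id)
  pmax(rate, 0)
}

#' Generate Poisson spike trains for all units and trials
#'
#' Inhomogeneous Poisson sampling of [rateProfile()] by thinning: per
#' unit and trial, candidate events are drawn from a homogeneous Poisson
#' process at an upper rate bound and accepted with probability
#' rate(t)/bound. Spike times run from trial start to movement offset plus
#' a short buffer. Fully reproducible under `seed`.
#'
#' @param units data.frame from [sampleUnits()].
#' @param trials completed trials from [generateBehavior()].
#' @param config validated configuration.
#' @param seed integer seed.
#' @return data.frame with columns `unit_id`, `trial_id`, `time_ms`.
#' @export
generateSpikes <- function(units, trials, config, seed) {
  cfg <- validateConfig(config)
  commitment <- cfg$sim$commitment_gain
  buffer <- cfg$sim$timing$post_buffer
  withSeed(seed, {
    out <- vector("list", nrow(units))
    for (i in seq_len(nrow(units))) {
      unit <- units[i, ]
      tr <- trials[trials$session_id == unit$session_id, ]
      if (!nrow(tr)) next
      t_end <- tr$t_movement_off + buffer
      rmax <- unit$truth_baseline_rate +
        unit$truth_tuning_gain * (2 + max(1, commitment))
      n_cand <- rpois(nrow(tr), rmax * t_end / 1000)
      idx <- rep(seq_len(nrow(tr)), n_cand)
      tt <- runif(length(idx)) * t_end[idx]
      # column-indexed view: rateProfileMulti only needs these fields
      sub <- lapply(tr[c("precue_location", "prior_level",
                         "high_prior_rule", "trial_type",
                         "reach_direction", "t_precue_on",
                         "t_rulecue_on", "t_movement_off")],
                    `[`, idx)
      r <- rateProfileMulti(unit, sub, tt, commitment)
      keep <- runif(length(idx)) < r / rmax
      if (!any(keep)) next
      ord <- order(idx[keep], tt[keep])
      out[[i]] <- data.frame(
        unit_id = unit$unit_id,
        trial_id = tr$trial_id[idx[keep]][ord],
        time_ms = tt[keep][ord],
        stringsAsFactors = FALSE
      )
    }
    res <- do.call(rbind, out)
    if (is.null(res))
      res <- data.frame(unit_id = character(), trial_id = character(),
                        time_ms = numeric(), stringsAsFactors = FALSE)
    rownames(res) <- NULL
    res
  })
}

#' Simulate a complete synthetic dataset
#'
#' Runs the full generator: unit sampling, block-design trial planning,
#' behavior, and Poisson spike trains. A single root seed spawns named
#' child streams (`units`, `trials`, `behavior`, `spikes`) so each stage is
#' independently reproducible.
#'
#' @param config configuration overrides (see [validateConfig()]).
#' @param seed integer root seed.
#' @return a [ReachSession-class] whose units table carries `truth_*`
#'   ground-truth columns.
#' @examples
#' sess <- simulateSession(list(sim = list(n_units_per_area = 2,
#'                                         n_blocks = 3)), seed = 1)
#' sess
#' @export
simulateSession <- function(config = list(), seed = 1) {
  cfg <- validateConfig(config)
  units <- sampleUnits(cfg, childSeed(seed, "units"))
  trials <- planTrials(cfg, childSeed(seed, "trials"))
  trials <- generateBehavior(trials, cfg, childSeed(seed, "behavior"))
  spikes <- generateSpikes(units, trials, cfg, childSeed(seed, "spikes"))
  ReachSession(units, trials, spikes)
}
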