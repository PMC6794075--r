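#' Default pipeline configuration
#'
#' Two blocks of tunables. `sim` defines the synthetic study conditions:
#' task timing (fixation 500-1000 ms, pre-cue 500 ms, memory 500-1500 ms
#' uniform, rule-cue 250 ms), block design (8 successful trials per block,
#' 2 free-choice + 6 instructed, prior constant within a block), behavioral
#' bias parameters (logistic choice bias of 2.8 per unit prior level, i.e.
#' 89% follow choices at the strongest level), and the neural population
#' (per-area unit counts, UR/DR/untuned mixture, von-Mises lobe tunings,
#' multiplicative prior modulation linear in prior level, area x class
#' selection latencies). `analysis` holds the analysis constants: EPSP
#' kernel tau_g = 2 ms and tau_d = 50 ms, Gaussian sigma = 50 ms, 1 ms
#' grid, 5 Hz rate gate, selectivity alpha = 0.01, modulation alpha = 0.05,
#' bootstrap N = 1000, permutation N = 10000, dip-test Monte-Carlo
#' N = 10000, neural-distance velocity threshold 0.3, and the [0, 600] ms
#' post-rule-cue latency search window.
#'
#' @return a nested named list.
#' @export
defaultConfig <- function() {
  list(
    sim = list(
      n_units_per_area = 20,
      n_sessions = 2,
      n_blocks = 84,
      class_mixture = c(UR = 0.375, DR = 0.375, untuned = 0.25),
      baseline_rate_mean = 8,
      baseline_rate_sd_log = 0.4,
      tuning_gain_mean = 24,
      tuning_gain_sd_log = 0.3,
      tuning_width = 2,
      prior_slope_ur = 1.0,
      prior_slope_dr = 1.4,
      selection_latency = list(PMd_DR = 80, PMd_UR = 120,
                               PRR_DR = 130, PRR_UR = 180),
      selection_latency_jitter_sd = 10,
      commitment_gain = 0,
      timing = list(fixation_min = 500, fixation_max = 1000,
                    precue_dur = 500, memory_min = 500, memory_max = 1500,
                    rulecue_dur = 250, movement_dur = 300,
                    post_buffer = 300),
      behavior = list(choice_bias_slope = 2.8, rt_base = 400,
                      rt_congruency_effect = 40, rt_noise_sd = 0.12,
                      error_base = 0.03, error_congruency_slope = 0.25)
    ),
    analysis = list(
      tau_g = 2, tau_d = 50, sigma = 50, dt = 1,
      rate_gate_hz = 5, alpha_select = 0.01, alpha_modulation = 0.05,
      n_boot = 1000, n_perm = 10000, dip_n_boot = 10000,
      velocity_threshold = 0.3,
      mvt_window = c(0, 600),
      roc_min_trials = 5,
      latency_ratios = list(c(3, 3), c(5, 1))
    )
  )
}

mergeConfig <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]])) {
      base[[k]] <- mergeConfig(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

checkPositive <- function(cfg, keys, where) {
  for (k in keys) {
    v <- cfg[[k]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0))
      prStop("configValidationError", "%s$%s must be positive, got %s",
             where, k, toString(v))
  }
}

#' Validate and normalize a configuration
#'
#' Fills defaults for missing entries, rejects unknown keys and
#' out-of-range values. An empty input yields the full default
#' configuration.
#'
#' @param config nested named list of overrides (possibly empty).
#' @return the normalized configuration list.
#' @examples
#' cfg <- validateConfig(list(analysis = list(sigma = 25)))
#' cfg$analysis$sigma
#' @export
validateConfig <- function(config = list()) {
  defaults <- defaultConfig()
  if (!is.list(config))
    prStop("configValidationError", "config must be a list")
  unknownKeys <- function(given, known, where) {
    extra <- setdiff(names(given), known)
    if (length(extra))
      prStop("configValidationError", "unknown config key(s) in %s: %s",
             where, toString(extra))
  }
  unknownKeys(config, names(defaults), "config")
  for (blk in names(config)) {
    unknownKeys(config[[blk]], names(defaults[[blk]]), blk)
    for (sub in c("timing", "behavior", "selection_latency")) {
      if (blk == "sim" && is.list(config$sim[[sub]]))
        unknownKeys(config$sim[[sub]], names(defaults$sim[[sub]]),
                    paste0("sim$", sub))
    }
  }
  cfg <- mergeConfig(defaults, config)

  s <- cfg$sim
  checkPositive(s, c("n_units_per_area", "n_sessions", "n_blocks",
                     "baseline_rate_mean", "tuning_gain_mean",
                     "tuning_width"), "sim")
  if (s$n_units_per_area != round(s$n_units_per_area) ||
      s$n_blocks != round(s$n_blocks))
    prStop("configValidationError", "unit/block counts must be integers")
  mix <- s$class_mixture
  if (!all(c("UR", "DR", "untuned") %in% names(mix)) || any(mix < 0) ||
      abs(sum(mix) - 1) > 1e-6)
    prStop("configValidationError",
           "class_mixture must be named UR/DR/untuned proportions summing to 1")
  tm <- s$timing
  if (tm$fixation_min > tm$fixation_max || tm$memory_min > tm$memory_max)
    prStop("configValidationError", "timing ranges must be ordered")
  bh <- s$behavior
  if (bh$error_base < 0 || bh$error_base > 1)
    prStop("configValidationError", "error_base must be in [0, 1]")
  if (bh$rt_base <= 0 || bh$rt_base +
      abs(bh$rt_congruency_effect) * 0.75 >= 800)
    prStop("configValidationError",
           "rt_base plus congruency effects must stay within (0, 800) ms")

  a <- cfg$analysis
  checkPositive(a, c("tau_g", "tau_d", "sigma", "dt", "rate_gate_hz",
                     "n_boot", "n_perm", "dip_n_boot",
                     "velocity_threshold", "roc_min_trials"), "analysis")
  if (a$alpha_select <= 0 || a$alpha_select >= 1 ||
      a$alpha_modulation <= 0 || a$alpha_modulation >= 1)
    prStop("configValidationError", "alpha levels must be in (0, 1)")
  if (length(a$mvt_window) != 2 || a$mvt_window[1] >= a$mvt_window[2])
    prStop("configValidationError", "mvt_window must be an ordered pair")
  cfg
}

#' Read a configuration file (YAML)
#'
#' @param path YAML file of overrides; keys mirror [defaultConfig()].
#' @return validated configuration list.
#' @export
readConfig <- function(path) {
  if (!file.exists(path))
    prStop("configValidationError", "config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.null(raw$sim$class_mixture))
    raw$sim$class_mixture <- unlist(raw$sim$class_mixture)
  if (!is.null(raw$analysis$mvt_window))
    raw$analysis$mvt_window <- unlist(raw$analysis$mvt_window)
  if (!is.null(raw$analysis$latency_ratios))
    raw$analysis$latency_ratios <- lapply(raw$analysis$latency_ratios, unlist)
  validateConfig(raw)
}
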