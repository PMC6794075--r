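#' Sample a synthetic neural population with ground truth
#'
#' Draws units for each session and area with a mixture of three classes:
#' up-regulating (UR: a single goal lobe that grows with prior toward the
#' preferred direction), down-regulating (DR: lobes at both potential goals
#' with the disregarded goal's lobe suppressed in proportion to prior), and
#' untuned. Tuning lobes are truncated von-Mises bumps (peak 1 at the
#' preferred direction, exactly zero at and beyond +/- 90 degrees, so goals
#' orthogonal to a unit's PD axis evoke no prior modulation). Baseline
#' rates and lobe gains are log-normal across units; each unit gets an
#' area x class selection latency (ms after rule-cue onset at which its
#' activity transitions to single-goal movement coding) plus Gaussian
#' jitter.
#'
#' @param config validated configuration (see [validateConfig()]).
#' @param seed integer seed.
#' @return data.frame of unit records with `truth_*` columns.
#' @export
sampleUnits <- function(config, seed) {
  cfg <- validateConfig(config)
  s <- cfg$sim
  withSeed(seed, {
    rows <- list()
    for (sess in seq_len(s$n_sessions)) {
      subject <- paste0("M", (sess - 1L) %% 2L + 1L)
      for (area in c("PMd", "PRR")) {
        n <- s$n_units_per_area
        klass <- sample(names(s$class_mixture), n, replace = TRUE,
                        prob = s$class_mixture)
        lat_key <- paste(area, ifelse(klass == "untuned", "UR", klass),
                         sep = "_")
        lat_base <- unlist(s$selection_latency[lat_key], use.names = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          unit_id = sprintf("s%d_%s_u%02d", sess, area, seq_len(n)),
          session_id = paste0("sess", sess),
          subject_id = subject,
          area = area,
          truth_klass = klass,
          # PDs at the four sampled directions: keeps direction roles
          # exact so orthogonal goals evoke no modulation by construction
          truth_pd = sample(CARDINAL_DIRECTIONS, n, replace = TRUE),
          truth_baseline_rate = rlnorm(n, log(s$baseline_rate_mean),
                                       s$baseline_rate_sd_log),
          truth_tuning_gain = ifelse(
            klass == "untuned", 0,
            rlnorm(n, log(s$tuning_gain_mean), s$tuning_gain_sd_log)),
          truth_tuning_width = s$tuning_width,
          truth_prior_slope = ifelse(klass == "UR", s$prior_slope_ur,
                                     ifelse(klass == "DR", s$prior_slope_dr, 0)),
          truth_selection_latency = pmax(
            10, lat_base + rnorm(n, 0, s$selection_latency_jitter_sd)),
          stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, rows)
  })
}

# Truncated von-Mises lobe: peak 1 at 0 deg, exactly 0 at and beyond 90 deg.
vonMisesLobe <- function(thetaDeg, kappa) {
  v <- exp(kappa * (cos(thetaDeg * pi / 180) - 1))
  v90 <- exp(-kappa)
  pmax(0, (v - v90) / (1 - v90)) * (angleDistance(thetaDeg, 0) <= 90)
}
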