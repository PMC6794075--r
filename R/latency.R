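#' Prepare per-unit condition-averaged density differences for neural
#' distances
#'
#' For every unit and pre-cue location, averages Gaussian-kernel spike
#' densities (aligned to rule-cue onset, per-unit normalized by the
#' full-prior PD_max planning response) separately for trials reaching
#' the counter-clockwise vs the clockwise goal, and stores their
#' difference. The Euclidean norm of these differences across units is
#' the neural distance; keeping the per-unit components allows unit
#' resampling (bootstrap) and reassignment (permutation) without
#' recomputing densities.
#'
#' @param session a [ReachSession-class].
#' @param gating output of [gateMotorGoalUnits()].
#' @param config validated configuration (Gaussian sigma, dt).
#' @param units optional unit subset (defaults to all gated units).
#' @param priorLevels prior levels to include (default all).
#' @param congruency `"follow"`, `"against"` or `"all"`.
#' @param trialType `"instructed"`, `"free_choice"` or `"all"`.
#' @param window time window in ms relative to rule-cue onset.
#' @return object of class `ndInput`: list with `time`, `diff` (array
#'   units x time x locations), `unit_ids`, `n_trials` (locations x 2
#'   goal columns), `dropped` (locations without both goals).
#' @export
neuralDistanceInput <- function(session, gating, config = list(),
                                units = NULL, priorLevels = NULL,
                                congruency = "all", trialType = "all",
                                window = c(-200, 800)) {
  cfg <- validateConfig(config)
  kern <- makeKernel("gaussian", sigma = cfg$analysis$sigma,
                     dt = cfg$analysis$dt)
  tr <- trialTable(session)
  sp <- spikeTable(session)
  gated <- gating[gating$gated, ]
  if (!is.null(units)) gated <- gated[gated$unit_id %in% units, ]
  keep <- tr$outcome == "correct"
  if (!is.null(priorLevels)) keep <- keep & tr$prior_level %in% priorLevels
  if (congruency != "all") keep <- keep & tr$congruency == congruency
  if (trialType != "all") keep <- keep & tr$trial_type == trialType
  tr <- tr[keep, ]
  if (!nrow(tr))
    prStop("emptyTraceError", "no trials match the requested condition")

  # normalization anchors (full-prior PD_max planning response)
  anchors <- modulationAnchors(session, gated)
  ok <- is.finite(anchors) & anchors > 0
  gated <- gated[ok, ]
  anchors <- anchors[ok]

  grid <- densityGrid(window, kern$dt)
  nU <- nrow(gated); nT <- length(grid)
  locs <- CARDINAL_DIRECTIONS
  diffs <- array(NA_real_, c(nU, nT, length(locs)),
                 dimnames = list(gated$unit_id, NULL, locs))
  n_trials <- matrix(0L, length(locs), 2,
                     dimnames = list(locs, c("ccw", "cw")))
  # spikes re-expressed relative to rule-cue onset, split per unit
  keep_sp <- sp$trial_id %in% tr$trial_id
  align <- setNames(tr$t_rulecue_on, tr$trial_id)
  sp_rel <- data.frame(unit_id = sp$unit_id[keep_sp],
                       trial_id = sp$trial_id[keep_sp],
                       rel = sp$time_ms[keep_sp] -
                         align[sp$trial_id[keep_sp]])
  sp_unit <- split(sp_rel[, c("trial_id", "rel")], sp_rel$unit_id)
  # condition averages use each unit's own session's trials
  un <- unitTable(session)
  unit_sess <- un$session_id[match(gated$unit_id, un$unit_id)]
  sessions <- unique(unit_sess)
  side_ids <- lapply(sessions, function(ss) {
    lapply(seq_along(locs), function(li) {
      loc <- locs[li]
      lapply(c(90, -90), function(rot)
        tr$trial_id[tr$session_id == ss & tr$precue_location == loc &
                      tr$reach_direction == wrapAngle(loc + rot)])
    })
  })
  names(side_ids) <- sessions
  for (li in seq_along(locs)) {
    n_trials[li, ] <- Reduce(`+`, lapply(sessions, function(ss)
      lengths(side_ids[[ss]][[li]])))
  }
  # a location enters the ND only if every contributing session has
  # trials reaching both opposing goals there
  loc_ok <- vapply(seq_along(locs), function(li)
    all(vapply(sessions, function(ss)
      all(lengths(side_ids[[ss]][[li]]) > 0), logical(1))), logical(1))
  for (ui in seq_len(nU)) {
    spu <- sp_unit[[gated$unit_id[ui]]]
    by_trial <- if (is.null(spu)) list()
      else split(spu$rel, spu$trial_id)
    for (li in which(loc_ok)) {
      sides <- side_ids[[unit_sess[ui]]][[li]]
      # trial-mean density = density of the pooled spikes / n trials
      avg <- lapply(sides, function(ids) {
        pooled <- unlist(by_trial[as.character(ids)], use.names = FALSE)
        if (is.null(pooled)) pooled <- numeric()
        densityMatrix(list(pooled), kern, window)$values[1, ] /
          length(ids)
      })
      diffs[ui, , li] <- (avg[[1]] - avg[[2]]) / anchors[ui]
    }
  }
  kept <- apply(!is.na(diffs[, 1, , drop = FALSE]), 3, all)
  structure(list(time = grid,
                 diff = diffs[, , kept, drop = FALSE],
                 unit_ids = gated$unit_id,
                 n_trials = n_trials,
                 dropped = locs[!kept]),
            class = "ndInput")
}

# full-prior PD_max planning response per gated unit (Hz)
modulationAnchors <- function(session, gated) {
  tr <- trialTable(session)
  keep <- tr$outcome == "correct" & tr$trial_type == "instructed" &
    tr$prior_level == 0.75
  rates <- epochRateMatrix(session, "planning")[, keep, drop = FALSE]
  tr <- tr[keep, ]
  vapply(seq_len(nrow(gated)), function(i) {
    r <- rates[gated$unit_id[i], ]
    sel <- is.finite(r) & tr$reach_direction == gated$pd_max[i]
    mean(r[sel])
  }, numeric(1))
}

#' Neural-distance trajectory
#'
#' Per time bin, the Euclidean norm across units of the difference
#' between the condition-averaged normalized densities of the two
#' opposing reach goals, averaged across the four pre-cue locations.
#'
#' @param ndInput from [neuralDistanceInput()].
#' @param units optional character/integer subset of units.
#' @return data.frame with `time` and `nd`; per-location components in
#'   attribute `components`.
#' @export
neuralDistance <- function(ndInput, units = NULL) {
  D <- ndInput$diff
  if (!is.null(units)) D <- D[units, , , drop = FALSE]
  comp <- apply(D, 3, function(m) sqrt(colSums(m^2, na.rm = TRUE)))
  nd <- rowMeans(comp)
  out <- data.frame(time = ndInput$time, nd = nd)
  attr(out, "components") <- comp
  attr(out, "n_units") <- dim(D)[1]
  out
}

#' Selection-signal latencies from a neural-distance trajectory
#'
#' Velocity is the centered finite difference of the trajectory per ms.
#' MVT (maximal velocity time) is the earliest time within the search
#' window at which the velocity attains its maximum (earliest bin wins
#' ties). PT (plateau time) is the first bin after MVT where the velocity
#' drops below the threshold. A flat or non-increasing trajectory yields
#' a no-latency flag (NA latencies).
#'
#' @param nd data.frame from [neuralDistance()] (columns `time`, `nd`),
#'   or a numeric trajectory with `time` supplied separately.
#' @param time optional time axis if `nd` is numeric.
#' @param window search window in ms (default c(0, 600) after rule-cue
#'   onset).
#' @param threshold plateau velocity threshold (distance units per ms,
#'   default 0.3).
#' @return list with `mvt`, `pt`, `max_velocity`, `found` (logical).
#' @export
latencyEstimates <- function(nd, time = NULL, window = c(0, 600),
                             threshold = 0.3) {
  if (is.data.frame(nd)) { time <- nd$time; nd <- nd$nd }
  stopifnot(length(time) == length(nd))
  n <- length(nd)
  if (n < 3) return(list(mvt = NA_real_, pt = NA_real_,
                         max_velocity = NA_real_, found = FALSE))
  dt <- time[2] - time[1]
  vel <- c(NA, (nd[3:n] - nd[1:(n - 2)]) / (2 * dt), NA)
  inwin <- which(time >= window[1] & time <= window[2] & is.finite(vel))
  if (!length(inwin)) return(list(mvt = NA_real_, pt = NA_real_,
                                  max_velocity = NA_real_, found = FALSE))
  vmax <- max(vel[inwin])
  if (!is.finite(vmax) || vmax <= 0)
    return(list(mvt = NA_real_, pt = NA_real_, max_velocity = vmax,
                found = FALSE))
  i_mvt <- inwin[which(vel[inwin] >= vmax - 1e-12)[1]]
  mvt <- time[i_mvt]
  after <- which(time > mvt & is.finite(vel) & vel < threshold)
  pt <- if (length(after)) time[after[1]] else NA_real_
  list(mvt = mvt, pt = pt, max_velocity = vmax, found = TRUE)
}

#' Bootstrap confidence bands for neural-distance latencies
#'
#' Resamples units with replacement, recomputes the neural distance and
#' its latencies, and returns percentile confidence intervals (90% by
#' default, matching the reporting convention for MVT CIs).
#'
#' @param ndInput from [neuralDistanceInput()].
#' @param nBoot number of bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @param level CI level (default 0.9).
#' @param window,threshold passed to [latencyEstimates()].
#' @return list with `mvt_ci`, `pt_ci`, `mvt_boot`, `pt_boot`, and the
#'   point estimates under `estimate`.
#' @export
bootstrapND <- function(ndInput, nBoot = 1000, seed = 1, level = 0.9,
                        window = c(0, 600), threshold = 0.3) {
  nU <- dim(ndInput$diff)[1]
  est <- latencyEstimates(neuralDistance(ndInput), window = window,
                          threshold = threshold)
  M2 <- squaredDiffMatrix(ndInput)
  nT <- length(ndInput$time); nL <- dim(ndInput$diff)[3]
  boots <- withSeed(seed, {
    vapply(seq_len(nBoot), function(b) {
      idx <- sample.int(nU, nU, replace = TRUE)
      nd <- ndFromSums(colSums(M2[idx, , drop = FALSE]), nT, nL)
      le <- latencyEstimates(nd, ndInput$time, window, threshold)
      c(le$mvt, le$pt)
    }, numeric(2))
  })
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  list(estimate = est,
       mvt_ci = quantile(boots[1, ], qs, na.rm = TRUE, names = FALSE),
       pt_ci = quantile(boots[2, ], qs, na.rm = TRUE, names = FALSE),
       mvt_boot = boots[1, ], pt_boot = boots[2, ])
}

# units x (time * location) matrix of squared differences
squaredDiffMatrix <- function(ndInput) {
  D <- ndInput$diff
  dm <- dim(D)
  matrix(D^2, nrow = dm[1])
}

ndFromSums <- function(sums, nT, nL) {
  rowMeans(matrix(sqrt(pmax(sums, 0)), nrow = nT))
}

#' Permutation test of latency differences between two populations
#'
#' Pools the units of both populations, repeatedly reassigns them at
#' random to two sets matching the original sizes, and recomputes the
#' MVT (and PT) difference. The p-value is the fraction of permutations
#' with an absolute latency difference at least as large as observed
#' (two-sided by construction of the symmetric reassignment).
#'
#' @param ndInputA,ndInputB `ndInput` objects on the same grid and
#'   locations (e.g. the two areas within one neuron class).
#' @param nPerm number of permutations (default 10000).
#' @param seed integer seed.
#' @param window,threshold passed to [latencyEstimates()].
#' @return list with observed latencies and differences, `p_mvt`,
#'   `p_pt`, `n_perm`.
#' @export
permutationAreaTest <- function(ndInputA, ndInputB, nPerm = 10000,
                                seed = 1, window = c(0, 600),
                                threshold = 0.3) {
  if (nPerm < 100)
    warning("fewer than 100 permutations gives a coarse p-value")
  stopifnot(length(ndInputA$time) == length(ndInputB$time))
  nT <- length(ndInputA$time)
  nLA <- dim(ndInputA$diff)[3]; nLB <- dim(ndInputB$diff)[3]
  if (nLA != nLB)
    prStop("alignmentError",
           "populations have different location coverage")
  nA <- dim(ndInputA$diff)[1]; nB <- dim(ndInputB$diff)[1]
  if (nA == 0 || nB == 0)
    prStop("emptyTraceError", "both unit sets must be non-empty")
  MA <- squaredDiffMatrix(ndInputA); MB <- squaredDiffMatrix(ndInputB)
  M <- rbind(MA, MB)
  tot <- colSums(M)
  lat <- function(sums) {
    le <- latencyEstimates(ndFromSums(sums, nT, nLA), ndInputA$time,
                           window, threshold)
    c(le$mvt, le$pt)
  }
  obsA <- lat(colSums(MA)); obsB <- lat(colSums(MB))
  obs <- abs(obsA - obsB)
  perms <- withSeed(seed, {
    vapply(seq_len(nPerm), function(b) {
      idxA <- sample.int(nA + nB, nA)
      sA <- colSums(M[idxA, , drop = FALSE])
      abs(lat(sA) - lat(tot - sA))
    }, numeric(2))
  })
  list(mvt_a = obsA[1], mvt_b = obsB[1], pt_a = obsA[2], pt_b = obsB[2],
       mvt_diff = obsA[1] - obsB[1], pt_diff = obsA[2] - obsB[2],
       p_mvt = mean(perms[1, ] >= obs[1] - 1e-12, na.rm = TRUE),
       p_pt = if (is.finite(obs[2]))
         mean(perms[2, ] >= obs[2] - 1e-12, na.rm = TRUE) else NA_real_,
       n_perm = as.integer(nPerm))
}
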