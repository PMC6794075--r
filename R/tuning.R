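#' Per-epoch firing-rate matrix
#'
#' Spike counts per unit and trial in one analysis window (see
#' [epochWindows()]), divided by the window length, computed for all units
#' and trials at once.
#'
#' @param session a [ReachSession-class].
#' @param epoch one of `"baseline"`, `"precue"`, `"planning"`,
#'   `"movement"`.
#' @return numeric matrix (units x trials) of rates in Hz, with unit and
#'   trial ids as dimnames.
#' @export
epochRateMatrix <- function(session,
                            epoch = c("baseline", "precue", "planning",
                                      "movement")) {
  epoch <- match.arg(epoch)
  w <- epochWindows()
  w <- w[w$name == epoch, ]
  tr <- trialTable(session)
  un <- unitTable(session)
  sp <- spikeTable(session)
  anchor <- tr[[paste0("t_", w$anchor_event)]]
  if (epoch == "movement") {
    start <- tr$t_movement_on
    end <- tr$t_movement_off
  } else {
    start <- anchor + w$offset_start
    end <- anchor + w$offset_end
  }
  nU <- nrow(un); nT <- nrow(tr)
  counts <- matrix(0L, nU, nT, dimnames = list(un$unit_id, tr$trial_id))
  if (nrow(sp)) {
    ui <- match(sp$unit_id, un$unit_id)
    ti <- match(sp$trial_id, tr$trial_id)
    inw <- sp$time_ms >= start[ti] & sp$time_ms < end[ti]
    code <- (ui[inw] - 1L) * nT + ti[inw]
    counts[] <- matrix(tabulate(code, nbins = nU * nT),
                       nrow = nU, byrow = TRUE)
  }
  len_s <- (end - start) / 1000
  rates <- sweep(counts, 2L, len_s, "/")
  # a unit is only observed in its own session's trials
  mismatch <- outer(un$session_id, tr$session_id, "!=")
  rates[mismatch] <- NA_real_
  rates
}

#' Directional tuning vector
#'
#' Vector sum of the four cardinal unit vectors weighted by the mean rate
#' per direction. The vector's angle is the continuous preferred
#' direction; its magnitude is zero for untuned (symmetric) responses, in
#' which case the angle is flagged undefined.
#'
#' @param meanRates named numeric of mean rates (Hz); names are direction
#'   degrees (default the four cardinals in order).
#' @param directions directions in degrees matching `meanRates`.
#' @return list with `vector` (x, y), `magnitude`, `angle` (degrees in
#'   [0, 360), NA if undefined) and `defined` (logical).
#' @examples
#' directionalTuningVector(c(8, 4, 2, 4)) # points at 0 degrees
#' @export
directionalTuningVector <- function(meanRates,
                                    directions = CARDINAL_DIRECTIONS) {
  stopifnot(length(meanRates) == length(directions))
  rad <- directions * pi / 180
  v <- c(x = sum(meanRates * cos(rad)), y = sum(meanRates * sin(rad)))
  mag <- sqrt(sum(v^2))
  defined <- mag > 1e-9
  ang <- if (defined) wrapAngle(atan2(v[["y"]], v[["x"]]) * 180 / pi)
         else NA_real_
  list(vector = v, magnitude = mag, angle = ang, defined = defined)
}

#' Kruskal-Wallis test of direction selectivity
#'
#' Tests per-trial firing rates against the direction factor. Degenerate
#' inputs (all rates identical) give p = 1; directions with fewer than
#' `minTrials` trials flag the unit as untestable rather than erroring.
#'
#' @param rates per-trial rates (Hz).
#' @param directions per-trial direction labels.
#' @param minTrials minimum trials per direction (default 2).
#' @return list with `p` (p-value or NA), `testable` (logical).
#' @export
selectivityTest <- function(rates, directions, minTrials = 2) {
  tab <- table(directions)
  if (length(tab) < 2 || any(tab < minTrials))
    return(list(p = NA_real_, testable = FALSE))
  if (max(rates) - min(rates) < 1e-12)
    return(list(p = 1, testable = TRUE))
  p <- kruskal.test(rates, factor(directions))$p.value
  if (is.nan(p)) p <- 1
  list(p = p, testable = TRUE)
}

#' Per-unit directional tuning in one epoch
#'
#' Mean rates per direction (pre-cue location for baseline/pre-cue epochs,
#' reach-goal direction for planning/movement), the directional tuning
#' vector, the discrete preferred direction PD_max (ties broken toward the
#' continuous DTV angle), and the Kruskal-Wallis selectivity p-value.
#' Computed on successful full-prior instructed trials, where the motor
#' goal is announced by the pre-cue.
#'
#' @param session a [ReachSession-class].
#' @param epoch analysis window name.
#' @param alpha selectivity level (default 0.01).
#' @return data.frame, one row per unit: mean rate per direction
#'   (`rate_0` ... `rate_270`), `dtv_x`, `dtv_y`, `dtv_magnitude`,
#'   `pd_continuous`, `pd_max`, `kw_p`, `is_selective`, `testable`.
#' @export
unitTuning <- function(session, epoch = "planning", alpha = 0.01) {
  tr <- trialTable(session)
  un <- unitTable(session)
  keep <- tr$prior_level == 0.75 & tr$trial_type == "instructed" &
    tr$outcome == "correct"
  rates <- epochRateMatrix(session, epoch)[, keep, drop = FALSE]
  dircol <- if (epoch %in% c("baseline", "precue")) "precue_location"
            else "reach_direction"
  dirs <- tr[[dircol]][keep]
  rows <- lapply(seq_len(nrow(un)), function(i) {
    r <- rates[i, ]
    obs <- is.finite(r)
    mr <- vapply(CARDINAL_DIRECTIONS,
                 function(d) mean(r[obs & dirs == d]), numeric(1))
    dtv <- directionalTuningVector(mr)
    st <- selectivityTest(r[obs], dirs[obs])
    pdm <- pdMaxOf(mr, dtv$angle)
    data.frame(unit_id = un$unit_id[i], epoch = epoch,
               rate_0 = mr[1], rate_90 = mr[2], rate_180 = mr[3],
               rate_270 = mr[4],
               dtv_x = dtv$vector[["x"]], dtv_y = dtv$vector[["y"]],
               dtv_magnitude = dtv$magnitude,
               pd_continuous = dtv$angle, pd_max = pdm,
               kw_p = st$p, testable = st$testable,
               is_selective = isTRUE(st$testable) & !is.na(st$p) &
                 st$p < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Discrete preferred direction: direction of maximal mean rate, ties
# broken toward the continuous DTV angle.
pdMaxOf <- function(meanRates, dtvAngle) {
  mx <- max(meanRates)
  cand <- CARDINAL_DIRECTIONS[meanRates >= mx - 1e-12]
  if (length(cand) > 1 && !is.na(dtvAngle))
    cand <- cand[which.min(angleDistance(cand, dtvAngle))]
  cand[1]
}

#' Gate motor-goal neurons
#'
#' Keeps units with (i) a mean epoch rate above the rate gate (default
#' 5 Hz) in at least one of the four analysis windows and (ii) significant
#' planning-period selectivity for the reach goal (Kruskal-Wallis
#' p < alpha, default 0.01) in successful full-prior instructed trials.
#'
#' @param session a [ReachSession-class].
#' @param config validated configuration (uses `analysis$rate_gate_hz`,
#'   `analysis$alpha_select`).
#' @return data.frame: planning [unitTuning()] columns plus
#'   `max_epoch_rate`, `passes_rate_gate` and `gated` (the motor-goal
#'   neuron flag); attribute `counts` holds per-area totals.
#' @export
gateMotorGoalUnits <- function(session, config = list()) {
  cfg <- validateConfig(config)
  un <- unitTable(session)
  tr <- trialTable(session)
  if (!any(tr$prior_level == 0.75 & tr$trial_type == "instructed" &
           tr$outcome == "correct"))
    prStop("gatingError", "no successful full-prior instructed trials")
  maxrate <- rep(0, nrow(un))
  for (ep in epochWindows()$name) {
    m <- epochRateMatrix(session, ep)
    maxrate <- pmax(maxrate, rowMeans(m, na.rm = TRUE))
  }
  tun <- unitTuning(session, "planning", alpha = cfg$analysis$alpha_select)
  tun$max_epoch_rate <- maxrate
  tun$passes_rate_gate <- maxrate > cfg$analysis$rate_gate_hz
  tun$gated <- tun$passes_rate_gate & tun$is_selective
  tun$area <- un$area[match(tun$unit_id, un$unit_id)]
  counts <- as.data.frame(table(area = tun$area, gated = tun$gated))
  attr(tun, "counts") <- counts
  tun
}

#' Trigonometric interpolation of a 4-direction tuning curve
#'
#' Reconstructs a continuous tuning curve from the four cardinal samples
#' by ideal low-pass (DFT-based) interpolation: mean, first harmonic, and
#' the Nyquist second-harmonic cosine at half weight (its sine is
#' unobservable at N = 4). The curve passes exactly through the samples.
#' Interpolation is presentation-layer only; statistical analyses use the
#' four sampled directions.
#'
#' @param samples numeric(4): responses at 0, 90, 180, 270 degrees.
#' @return a function of direction (degrees, vectorized).
#' @examples
#' f <- interpolateTuning(c(1, 0, -1, 0))
#' all.equal(f(60), cos(60 * pi / 180))
#' @export
interpolateTuning <- function(samples) {
  stopifnot(length(samples) == 4)
  a0 <- mean(samples)
  a1 <- (samples[1] - samples[3]) / 2
  b1 <- (samples[2] - samples[4]) / 2
  a2 <- (samples[1] - samples[2] + samples[3] - samples[4]) / 4
  function(thetaDeg) {
    th <- thetaDeg * pi / 180
    a0 + a1 * cos(th) + b1 * sin(th) + a2 * cos(2 * th)
  }
}

# Role of a direction relative to a unit's discrete preferred direction.
directionRole <- function(direction, pdMax) {
  d <- angleDistance(direction, pdMax)
  ifelse(d <= 1e-9, "PD_max", ifelse(abs(d - 180) <= 1e-9, "OD", "Orth"))
}

#' PD-aligned normalized population tuning per prior level
#'
#' For each motor-goal neuron, planning-period mean rates are computed as
#' a function of the high-prior goal direction (the cw goal stands in as
#' the prior direction in the zero-prior condition), aligned so the
#' unit's PD_max maps to 0 degrees, normalized by the unit's full-prior
#' response at aligned 0, then averaged across units with standard
#' errors.
#'
#' @param session a [ReachSession-class].
#' @param gating output of [gateMotorGoalUnits()].
#' @param units optional character vector restricting the population.
#' @return data.frame: `prior_level`, `aligned_direction` (0/90/180/270),
#'   `mean`, `se`, `n_units`. Units without a positive full-prior anchor
#'   response are dropped with a warning.
#' @export
populationTuning <- function(session, gating, units = NULL) {
  tr <- ensureHighPriorRule(trialTable(session))
  keep <- tr$trial_type == "instructed" & tr$outcome == "correct"
  rates <- epochRateMatrix(session, "planning")[, keep, drop = FALSE]
  tr <- tr[keep, ]
  # direction of the higher prior; cw goal by convention at zero prior
  prior_goal <- ruleToDirection(
    ifelse(tr$high_prior_rule == "tie", "cw", tr$high_prior_rule),
    tr$precue_location)
  gated <- gating[gating$gated, ]
  if (!is.null(units)) gated <- gated[gated$unit_id %in% units, ]
  levels_ <- sort(unique(tr$prior_level))
  dropped <- character()
  acc <- list()
  for (i in seq_len(nrow(gated))) {
    uid <- gated$unit_id[i]
    r <- rates[uid, ]
    obs <- is.finite(r)
    aligned <- wrapAngle(prior_goal - gated$pd_max[i])
    anchor <- mean(r[obs & tr$prior_level == 0.75 & aligned == 0])
    if (!is.finite(anchor) || anchor <= 0) {
      dropped <- c(dropped, uid)
      next
    }
    for (lev in levels_) for (ad in CARDINAL_DIRECTIONS) {
      sel <- obs & tr$prior_level == lev & aligned == ad
      if (!any(sel)) next
      acc[[length(acc) + 1L]] <- data.frame(
        unit_id = uid, prior_level = lev, aligned_direction = ad,
        value = mean(r[sel]) / anchor, stringsAsFactors = FALSE)
    }
  }
  if (length(dropped))
    warning("units without positive full-prior anchor dropped: ",
            toString(dropped))
  if (!length(acc))
    return(data.frame(prior_level = numeric(), aligned_direction = numeric(),
                      mean = numeric(), se = numeric(),
                      n_units = integer()))
  d <- do.call(rbind, acc)
  out <- do.call(rbind, lapply(split(d, list(d$prior_level,
                                             d$aligned_direction)),
    function(g) data.frame(prior_level = g$prior_level[1],
                           aligned_direction = g$aligned_direction[1],
                           mean = mean(g$value),
                           se = sd(g$value) / sqrt(nrow(g)),
                           n_units = nrow(g))))
  out <- out[order(out$prior_level, out$aligned_direction), ]
  rownames(out) <- NULL
  out
}
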