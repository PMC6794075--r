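# Per-trial planning rates with prior-direction roles for modulation fits.
# Role = position of the high-prior goal relative to the unit's PD_max
# (PD_max / OD / Orth); in the zero-prior condition the cw goal stands in
# by convention and rows are flagged zero_prior (excluded from slope
# fits, used in condition summaries).
modulationData <- function(session, gating, units = NULL) {
  tr <- ensureHighPriorRule(trialTable(session))
  keep <- tr$outcome == "correct"
  rates <- epochRateMatrix(session, "planning")[, keep, drop = FALSE]
  tr <- tr[keep, ]
  prior_goal <- ruleToDirection(
    ifelse(tr$high_prior_rule == "tie", "cw", tr$high_prior_rule),
    tr$precue_location)
  gated <- gating[gating$gated, ]
  if (!is.null(units)) gated <- gated[gated$unit_id %in% units, ]
  out <- lapply(seq_len(nrow(gated)), function(i) {
    uid <- gated$unit_id[i]
    r <- rates[uid, ]
    obs <- is.finite(r)
    role <- directionRole(prior_goal, gated$pd_max[i])
    aligned0 <- wrapAngle(prior_goal - gated$pd_max[i]) == 0
    anchor <- mean(r[obs & tr$prior_level == 0.75 & aligned0])
    data.frame(unit_id = uid, trial_id = tr$trial_id[obs],
               rate = r[obs], norm_rate = r[obs] / anchor,
               prior_level = tr$prior_level[obs], role = role[obs],
               zero_prior = tr$prior_level[obs] == 0,
               trial_type = tr$trial_type[obs],
               stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, out)
  rownames(d) <- NULL
  d
}

#' Per-unit graded-modulation fit and class
#'
#' Ordinary least squares of trial-by-trial normalized planning rates on
#' prior level, prior direction (high prior toward the unit's PD_max vs
#' its OD) and their interaction, parameterized so the two marginal prior
#' slopes and their two-sided p-values are read off directly. The
#' modulation angle is `atan2(max(slope_pd, 0), max(-slope_od, 0))` —
#' upregulation on the y axis, downregulation magnitude on the x axis, so
#' wrong-sign slopes fall on an axis. A unit is classed UR if its PD_max
#' slope is significant and the angle exceeds pi/4, DR if its OD slope is
#' significant and the angle is below pi/4, and none otherwise; units
#' significant on both axes are additionally flagged `both_significant`.
#'
#' @param normRate normalized planning rates (one per trial).
#' @param priorLevel prior levels (zero-prior trials are ignored: prior
#'   direction is undefined there).
#' @param role `"PD_max"` or `"OD"` per trial (others ignored).
#' @param alpha per-slope significance level (default 0.05).
#' @return one-row data.frame: `slope_pd`, `slope_od`, `p_pd`, `p_od`,
#'   `angle` (radians in [0, pi/2]), `klass`, `both_significant`,
#'   `fittable`.
#' @export
fitUnitModulation <- function(normRate, priorLevel, role, alpha = 0.05) {
  keep <- role %in% c("PD_max", "OD") & priorLevel > 0 &
    is.finite(normRate)
  y <- normRate[keep]; lev <- priorLevel[keep]
  rl <- factor(role[keep], levels = c("PD_max", "OD"))
  unfit <- data.frame(slope_pd = NA_real_, slope_od = NA_real_,
                      p_pd = NA_real_, p_od = NA_real_, angle = NA_real_,
                      klass = "none", both_significant = FALSE,
                      fittable = FALSE, stringsAsFactors = FALSE)
  if (length(y) < 4 || length(unique(lev[rl == "PD_max"])) < 2 ||
      length(unique(lev[rl == "OD"])) < 2)
    return(unfit)
  fit <- lm(y ~ 0 + rl + rl:lev)
  sm <- coef(summary(fit))
  pd_term <- "rlPD_max:lev"; od_term <- "rlOD:lev"
  if (!all(c(pd_term, od_term) %in% rownames(sm))) return(unfit)
  slope_pd <- sm[pd_term, "Estimate"]
  slope_od <- sm[od_term, "Estimate"]
  p_pd <- sm[pd_term, "Pr(>|t|)"]
  p_od <- sm[od_term, "Pr(>|t|)"]
  up <- max(slope_pd, 0); down <- max(-slope_od, 0)
  angle <- if (up == 0 && down == 0) NA_real_ else atan2(up, down)
  sig_pd <- is.finite(p_pd) && p_pd < alpha
  sig_od <- is.finite(p_od) && p_od < alpha
  klass <- "none"
  if (sig_pd && !is.na(angle) && angle > pi / 4) klass <- "UR"
  else if (sig_od && !is.na(angle) && angle < pi / 4) klass <- "DR"
  data.frame(slope_pd = slope_pd, slope_od = slope_od, p_pd = p_pd,
             p_od = p_od, angle = angle, klass = klass,
             both_significant = sig_pd && sig_od, fittable = TRUE,
             stringsAsFactors = FALSE)
}

#' Classify all motor-goal neurons by prior modulation
#'
#' Runs [fitUnitModulation()] for every gated unit (normalized by the
#' unit's full-prior PD_max planning response) and tests the angular
#' distribution of graded units (significant on at least one axis) for
#' bimodality with the dip test, per area.
#'
#' @param session a [ReachSession-class].
#' @param gating output of [gateMotorGoalUnits()].
#' @param config validated configuration (`alpha_modulation`,
#'   `dip_n_boot`).
#' @param seed seed for the dip-test Monte-Carlo null.
#' @return data.frame of per-unit modulation results; attribute
#'   `dip` holds the per-area dip-test results, attribute `counts` the
#'   class table per area.
#' @export
classifyUnits <- function(session, gating, config = list(), seed = 1) {
  cfg <- validateConfig(config)
  alpha <- cfg$analysis$alpha_modulation
  md <- modulationData(session, gating)
  un <- unitTable(session)
  res <- do.call(rbind, lapply(split(md, md$unit_id), function(d) {
    cbind(data.frame(unit_id = d$unit_id[1], stringsAsFactors = FALSE),
          fitUnitModulation(d$norm_rate, d$prior_level, d$role, alpha))
  }))
  rownames(res) <- NULL
  res$area <- un$area[match(res$unit_id, un$unit_id)]
  dips <- lapply(split(res, res$area), function(g) {
    ang <- g$angle[g$klass != "none" | g$both_significant]
    ang <- ang[is.finite(ang)]
    if (length(ang) >= 4)
      dipTest(ang, nBoot = cfg$analysis$dip_n_boot,
              seed = childSeed(seed, paste0("dip_", g$area[1])))
    else list(dip = NA_real_, p = NA_real_, n_boot = 0L, seed = NA)
  })
  attr(res, "dip") <- dips
  attr(res, "counts") <- table(area = res$area, klass = res$klass)
  res
}

#' Population-level prior-modulation test
#'
#' Fixed-effect tests of prior on non-normalized planning rates at the
#' three prior-direction roles. The primary fit is a mixed model of rate
#' on prior x prior-direction (PD_max vs OD) with per-unit random slopes;
#' if it fails or is singular, a two-stage fallback (per-unit OLS slopes,
#' then one-sample t-tests across units) is used and flagged. Slopes at
#' orthogonal trials are always assessed by the two-stage route (they are
#' not part of the interaction model), and successive prior levels are
#' compared per role with Bonferroni-corrected t-tests.
#'
#' @param session a [ReachSession-class].
#' @param gating output of [gateMotorGoalUnits()].
#' @param units optional restriction to a unit subset (e.g. one area and
#'   class).
#' @return list with `slopes` (per-role across-unit slope tests),
#'   `mixed` (mixed-model coefficient table or NULL), `fallback`
#'   (logical), `posthoc` (successive prior-level contrasts per role).
#' @export
populationModulationTest <- function(session, gating, units = NULL) {
  md <- modulationData(session, gating, units)
  md_fit <- md[!md$zero_prior & md$role %in% c("PD_max", "OD"), ]

  mixed <- NULL
  fallback <- FALSE
  if (length(unique(md_fit$unit_id)) >= 2) {
    fit <- tryCatch({
      f <- suppressWarnings(suppressMessages(
        lme4::lmer(rate ~ prior_level * role +
                     (prior_level * role | unit_id),
                   data = md_fit,
                   control = lme4::lmerControl(calc.derivs = FALSE))))
      if (lme4::isSingular(f, tol = 1e-4)) fallback <- TRUE
      f
    }, error = function(e) { fallback <<- TRUE; NULL })
    if (!is.null(fit)) {
      cc <- coef(summary(fit))
      mixed <- data.frame(term = rownames(cc), estimate = cc[, "Estimate"],
                          t = cc[, "t value"], row.names = NULL)
    }
  } else fallback <- TRUE

  # two-stage: per-unit slope of rate on prior per role, pooled by t-test
  slopeRows <- lapply(c("PD_max", "OD", "Orth"), function(rr) {
    per_unit <- vapply(split(md, md$unit_id), function(d) {
      d <- d[!d$zero_prior & d$role == rr, ]
      if (nrow(d) < 3 || length(unique(d$prior_level)) < 2)
        return(NA_real_)
      coef(lm(rate ~ prior_level, data = d))[["prior_level"]]
    }, numeric(1))
    per_unit <- per_unit[is.finite(per_unit)]
    tt <- if (length(per_unit) >= 2) t.test(per_unit) else NULL
    data.frame(role = rr, mean_slope = mean(per_unit),
               n_units = length(per_unit),
               t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
               p = if (is.null(tt)) NA_real_ else tt$p.value,
               stringsAsFactors = FALSE)
  })
  slopes <- do.call(rbind, slopeRows)

  posthoc <- posthocByRole(md)
  list(slopes = slopes, mixed = mixed, fallback = fallback,
       posthoc = posthoc)
}

# Bonferroni-corrected t-tests between successive prior levels within
# each prior-direction role, across units (unit-mean rates per level).
posthocByRole <- function(md) {
  rows <- list()
  for (rr in c("PD_max", "OD", "Orth")) {
    d <- md[md$role == rr, ]
    agg <- do.call(rbind, lapply(split(d, list(d$unit_id, d$prior_level),
                                       drop = TRUE), function(g)
      data.frame(unit_id = g$unit_id[1], prior_level = g$prior_level[1],
                 rate = mean(g$rate), stringsAsFactors = FALSE)))
    levs <- sort(unique(agg$prior_level))
    if (length(levs) < 2) next
    k <- length(levs) - 1L
    for (i in seq_len(k)) {
      a <- agg[agg$prior_level == levs[i], c("unit_id", "rate")]
      b <- agg[agg$prior_level == levs[i + 1], c("unit_id", "rate")]
      mm <- merge(a, b, by = "unit_id")
      if (nrow(mm) < 2) next
      if (sd(mm$rate.x - mm$rate.y) < 1e-12) {
        p <- 1
      } else {
        p <- t.test(mm$rate.x, mm$rate.y, paired = TRUE)$p.value
      }
      rows[[length(rows) + 1L]] <- data.frame(
        role = rr, level_a = levs[i], level_b = levs[i + 1],
        p_raw = p, p_bonf = min(1, p * k),
        n_pairs = nrow(mm), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}
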