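#' Sort free-choice trials by prior and reach roles for one unit
#'
#' Each free-choice trial is labeled by where the higher prior pointed
#' relative to the unit's PD_max (`Prior-in` at PD_max, `Prior-out` at
#' OD, `Orth` otherwise; zero-prior trials get `neutral` and are excluded
#' from between-condition comparisons) and by whether the reach went into
#' or out of the PD_max (`Reach-in` / `Reach-out`; reaches orthogonal to
#' the PD axis are `Orth`). Prior-in followed by Reach-in and Prior-out
#' followed by Reach-out are follow trials; the cross combinations are
#' against trials.
#'
#' @param pdMax the unit's discrete preferred direction (degrees).
#' @param trials free-choice trials data.frame.
#' @return data.frame with `trial_id`, `prior_role`, `reach_role`,
#'   `congruency`, `prior_level`.
#' @export
sortChoiceTrials <- function(pdMax, trials) {
  trials <- ensureHighPriorRule(trials)
  fc <- trials[trials$trial_type == "free_choice" &
                 trials$outcome == "correct", ]
  prior_goal <- ruleToDirection(
    ifelse(fc$high_prior_rule == "tie", "cw", fc$high_prior_rule),
    fc$precue_location)
  prior_role <- ifelse(fc$prior_level == 0, "neutral",
                       c(PD_max = "Prior-in", OD = "Prior-out",
                         Orth = "Orth")[directionRole(prior_goal, pdMax)])
  reach_role <- c(PD_max = "Reach-in", OD = "Reach-out",
                  Orth = "Orth")[directionRole(fc$reach_direction, pdMax)]
  data.frame(trial_id = fc$trial_id, prior_role = unname(prior_role),
             reach_role = unname(reach_role),
             congruency = fc$congruency, prior_level = fc$prior_level,
             stringsAsFactors = FALSE)
}

#' Area under the ROC curve (rank-based)
#'
#' The probability that a random value from `a` exceeds a random value
#' from `b`, counting ties as 1/2 — equivalently the normalized
#' Mann-Whitney U statistic. 0.5 is chance discriminability, 1.0 perfect.
#'
#' @param a,b numeric samples for the two classes.
#' @param minN minimum trials per class (default 5); smaller classes
#'   return NA with an `ok = FALSE` flag.
#' @return list with `auc`, `n_a`, `n_b`, `ok`.
#' @examples
#' auroc(c(5, 6, 7), c(1, 2, 3), minN = 3)$auc # 1
#' @export
auroc <- function(a, b, minN = 5) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  na <- length(a); nb <- length(b)
  if (na < minN || nb < minN)
    return(list(auc = NA_real_, n_a = na, n_b = nb, ok = FALSE))
  r <- rank(c(a, b))
  auc <- (sum(r[seq_len(na)]) - na * (na + 1) / 2) / (na * nb)
  list(auc = auc, n_a = na, n_b = nb, ok = TRUE)
}

#' Choice-predictive ROC suite
#'
#' For every motor-goal neuron: the within-condition ROC (Reach-in vs
#' Reach-out discriminability of trial-by-trial planning activity,
#' separately in Prior-in and Prior-out trials — how well planning
#' activity predicts the upcoming follow/against choice) and the
#' between-condition ROC (Prior-in vs Prior-out — how well it reflects
#' the prior direction), per non-zero prior level and pooled. A
#' three-factor fixed-effect model of normalized planning activity on
#' prior x prior-direction x reach-direction with per-unit random
#' effects (two-stage fallback on singular fits) accompanies the ROC
#' table.
#'
#' @param session a [ReachSession-class].
#' @param gating output of [gateMotorGoalUnits()].
#' @param config validated configuration (`roc_min_trials`).
#' @return list with `roc` (per unit x comparison x level), `summary`
#'   (population means per comparison), `model` (factor-model report).
#' @export
choiceRocSuite <- function(session, gating, config = list()) {
  cfg <- validateConfig(config)
  minN <- cfg$analysis$roc_min_trials
  tr <- trialTable(session)
  rates <- epochRateMatrix(session, "planning")
  gated <- gating[gating$gated, ]
  anchors <- modulationAnchors(session, gated)
  rows <- list()
  model_rows <- list()
  for (i in seq_len(nrow(gated))) {
    uid <- gated$unit_id[i]
    srt <- sortChoiceTrials(gated$pd_max[i], tr)
    if (!nrow(srt)) next
    r <- rates[uid, srt$trial_id]
    addRoc <- function(comparison, level, a, b) {
      rc <- auroc(a, b, minN)
      rows[[length(rows) + 1L]] <<- data.frame(
        unit_id = uid, comparison = comparison, prior_level = level,
        auc = rc$auc, n_a = rc$n_a, n_b = rc$n_b, ok = rc$ok,
        stringsAsFactors = FALSE)
    }
    lev_sets <- c(as.list(sort(unique(srt$prior_level[
      srt$prior_level > 0]))), list("pooled"))
    for (lv in lev_sets) {
      sel <- if (identical(lv, "pooled")) srt$prior_level > 0
             else srt$prior_level == lv
      lvlab <- if (identical(lv, "pooled")) NA_real_ else lv
      pin <- sel & srt$prior_role == "Prior-in"
      pout <- sel & srt$prior_role == "Prior-out"
      addRoc("within_prior_in", lvlab,
             r[pin & srt$reach_role == "Reach-in"],
             r[pin & srt$reach_role == "Reach-out"])
      addRoc("within_prior_out", lvlab,
             r[pout & srt$reach_role == "Reach-in"],
             r[pout & srt$reach_role == "Reach-out"])
      addRoc("between_prior", lvlab, r[pin], r[pout])
    }
    keep <- srt$prior_role %in% c("Prior-in", "Prior-out") &
      srt$reach_role %in% c("Reach-in", "Reach-out")
    if (any(keep)) {
      model_rows[[length(model_rows) + 1L]] <- data.frame(
        unit_id = uid, act = r[keep] / anchors[i],
        prior_level = srt$prior_level[keep],
        prior_dir = srt$prior_role[keep],
        reach_dir = srt$reach_role[keep], stringsAsFactors = FALSE)
    }
  }
  roc <- do.call(rbind, rows)
  rownames(roc) <- NULL
  pooled <- roc[is.na(roc$prior_level) & roc$ok, ]
  summary <- if (nrow(pooled)) {
    out <- do.call(rbind, lapply(split(pooled, pooled$comparison),
      function(g) data.frame(comparison = g$comparison[1],
                             mean_auc = mean(g$auc), n_units = nrow(g))))
    rownames(out) <- NULL
    out
  } else NULL
  model <- NULL
  if (length(model_rows) >= 2) {
    md <- do.call(rbind, model_rows)
    md <- md[is.finite(md$act), ]
    model <- fitGroupedModel(
      act ~ prior_level * prior_dir * reach_dir,
      "(prior_level + prior_dir + reach_dir | unit_id)",
      md, group = "unit_id")
  }
  list(roc = roc, summary = summary, model = model)
}

# mixed fit with generic grouping + two-stage fallback
fitGroupedModel <- function(fixed, random, data, group) {
  fallback <- FALSE
  coefs <- NULL
  full <- stats::as.formula(paste(deparse(fixed), "+", random))
  fit <- tryCatch({
    f <- suppressWarnings(suppressMessages(
      lme4::lmer(full, data = data,
                 control = lme4::lmerControl(calc.derivs = FALSE))))
    if (lme4::isSingular(f, tol = 1e-4)) fallback <- TRUE
    f
  }, error = function(e) { fallback <<- TRUE; NULL })
  if (!is.null(fit) && !fallback) {
    sm <- coef(summary(fit))
    coefs <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                        se = sm[, "Std. Error"], t = sm[, "t value"],
                        p = 2 * pnorm(-abs(sm[, "t value"])),
                        row.names = NULL, stringsAsFactors = FALSE)
  }
  if (is.null(coefs)) {
    fallback <- TRUE
    d2 <- data
    d2$subject_id <- d2[[group]]
    coefs <- twoStageFit(fixed, d2)
  }
  list(coefficients = coefs, fallback = fallback, n = nrow(data))
}

#' Pairwise signal correlations by PD distance and prior
#'
#' Pearson correlation of planning-period rates across trials for every
#' pair of simultaneously recorded motor-goal neurons (same session),
#' per prior level, binned by the distance between the units' discrete
#' preferred directions (0, 90 or 180 degrees; 270 folds to 90). A
#' prior-trend model (correlation on prior level with pair random
#' slopes, two-stage fallback) is fitted for the opposite-PD (180
#' degree) bin, where co-planning of both goals predicts
#' anti-correlation that weakens as the prior grows.
#'
#' @param session a [ReachSession-class].
#' @param gating output of [gateMotorGoalUnits()].
#' @return list with `pairs` (per pair x level correlations) and
#'   `trend180` (model report or NULL).
#' @export
signalCorrelations <- function(session, gating) {
  tr <- trialTable(session)
  un <- unitTable(session)
  rates <- epochRateMatrix(session, "planning")
  gated <- gating[gating$gated, ]
  gated$session_id <- un$session_id[match(gated$unit_id, un$unit_id)]
  keep <- tr$outcome == "correct"
  rows <- list()
  for (sess in unique(gated$session_id)) {
    g <- gated[gated$session_id == sess, ]
    if (nrow(g) < 2) next
    tsel <- keep & tr$session_id == sess
    for (lev in sort(unique(tr$prior_level[tsel]))) {
      cols <- tsel & tr$prior_level == lev
      m <- rates[g$unit_id, cols, drop = FALSE]
      sds <- apply(m, 1, sd)
      cm <- suppressWarnings(cor(t(m)))
      for (i in seq_len(nrow(g) - 1)) for (j in (i + 1):nrow(g)) {
        if (!is.finite(sds[i]) || !is.finite(sds[j]) ||
            sds[i] == 0 || sds[j] == 0) next
        rows[[length(rows) + 1L]] <- data.frame(
          session_id = sess, unit_a = g$unit_id[i], unit_b = g$unit_id[j],
          pd_distance = angleDistance(g$pd_max[i], g$pd_max[j]),
          prior_level = lev, r = cm[i, j], n_trials = sum(cols),
          stringsAsFactors = FALSE)
      }
    }
  }
  pairs <- do.call(rbind, rows)
  trend <- NULL
  if (!is.null(pairs)) {
    rownames(pairs) <- NULL
    opp <- pairs[pairs$pd_distance == 180, ]
    opp$pair_id <- paste(opp$unit_a, opp$unit_b)
    if (nrow(opp) >= 8 && length(unique(opp$pair_id)) >= 2)
      trend <- fitGroupedModel(r ~ prior_level,
                               "(prior_level | pair_id)", opp,
                               group = "pair_id")
  }
  list(pairs = pairs, trend180 = trend)
}
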