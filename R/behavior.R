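#' Behavioral summary by prior level and congruency
#'
#' Error rates (instructed trials only — both goals are valid on free
#' choices), mean reaction times with standard errors per prior level x
#' congruency x trial type, and choice probabilities (fraction of
#' free-choice reaches toward the high-prior direction; in the zero-prior
#' condition cw reaches count as follow by convention).
#'
#' @param trials completed trials data.frame (or a [ReachSession-class]).
#' @return list with `conditions` (per-cell error rate, RT mean/SE, n)
#'   and `choice` (per-level choice probability with n).
#' @export
summarizeBehavior <- function(trials) {
  if (is(trials, "ReachSession")) trials <- trialTable(trials)
  tr <- trials[trials$outcome != "aborted", ]
  cells <- split(tr, list(tr$prior_level, tr$congruency, tr$trial_type),
                 drop = TRUE)
  conditions <- do.call(rbind, lapply(cells, function(g) {
    data.frame(
      prior_level = g$prior_level[1], congruency = g$congruency[1],
      trial_type = g$trial_type[1],
      n = nrow(g),
      error_rate = if (g$trial_type[1] == "instructed")
        mean(g$outcome == "error") else NA_real_,
      rt_mean = mean(g$rt), rt_se = sd(g$rt) / sqrt(nrow(g)),
      stringsAsFactors = FALSE)
  }))
  rownames(conditions) <- NULL
  fc <- tr[tr$trial_type == "free_choice", ]
  choice <- do.call(rbind, lapply(split(fc, fc$prior_level), function(g) {
    data.frame(prior_level = g$prior_level[1], n = nrow(g),
               choice_probability = mean(g$congruency == "follow"))
  }))
  rownames(choice) <- NULL
  list(conditions = conditions[order(conditions$trial_type,
                                     conditions$congruency,
                                     conditions$prior_level), ],
       choice = choice)
}

# Two-stage fallback for mixed models: per-subject GLM, fixed effects
# pooled by inverse variance, z-tests.
twoStageFit <- function(formula, data, family = NULL) {
  per <- lapply(split(data, data$subject_id), function(d) {
    fit <- tryCatch({
      if (is.null(family)) lm(formula, data = d)
      else suppressWarnings(glm(formula, data = d, family = family))
    }, error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    sm <- coef(summary(fit))
    data.frame(term = rownames(sm), est = sm[, 1], se = sm[, 2],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  per <- per[!vapply(per, is.null, logical(1))]
  if (!length(per)) return(NULL)
  all_terms <- unique(unlist(lapply(per, `[[`, "term")))
  out <- do.call(rbind, lapply(all_terms, function(tm) {
    est <- unlist(lapply(per, function(p) p$est[p$term == tm]))
    se <- unlist(lapply(per, function(p) p$se[p$term == tm]))
    ok <- is.finite(est) & is.finite(se) & se > 0
    est <- est[ok]; se <- se[ok]
    if (!length(est)) return(NULL)
    wgt <- 1 / se^2
    pooled <- sum(wgt * est) / sum(wgt)
    pse <- sqrt(1 / sum(wgt))
    z <- pooled / pse
    data.frame(term = tm, estimate = pooled, se = pse, t = z,
               p = 2 * pnorm(-abs(z)), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

fitOneModel <- function(id, fixed, random, data, family = NULL) {
  fallback <- FALSE
  coefs <- NULL
  n_subj <- length(unique(data$subject_id))
  if (n_subj >= 2) {
    full <- stats::as.formula(paste(deparse(fixed), "+", random))
    fit <- tryCatch({
      f <- if (is.null(family))
        suppressWarnings(suppressMessages(lme4::lmer(full, data = data)))
      else
        suppressWarnings(suppressMessages(
          lme4::glmer(full, data = data, family = family)))
      if (lme4::isSingular(f, tol = 1e-4)) fallback <- TRUE
      f
    }, error = function(e) { fallback <<- TRUE; NULL })
    if (!is.null(fit) && !fallback) {
      sm <- coef(summary(fit))
      p <- if ("Pr(>|z|)" %in% colnames(sm)) sm[, "Pr(>|z|)"]
           else 2 * pnorm(-abs(sm[, "t value"]))
      coefs <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                          se = sm[, "Std. Error"],
                          t = sm[, 3], p = p, row.names = NULL,
                          stringsAsFactors = FALSE)
    }
  } else fallback <- TRUE
  if (is.null(coefs)) {
    fallback <- TRUE
    coefs <- twoStageFit(fixed, data, family)
  }
  list(model = id, coefficients = coefs, fallback = fallback,
       n = nrow(data))
}

#' Fit the behavioral-bias regression models
#'
#' Three models: error rates and reaction times on
#' `PRIOR + PRIOR:CONGRUENCY` (prior effect split by congruency, no
#' congruency main effect) with subject random slopes — binomial for
#' errors, identity for RT — and free-choice follow/against on `PRIOR`
#' (binomial) with subject random slopes. Mixed fits use lme4; a
#' singular or failed fit falls back to the documented two-stage
#' per-subject route and is flagged.
#'
#' @param trials completed trials data.frame (or [ReachSession-class]).
#' @return list of model reports (`M1_error`, `M1_rt`, `M2_choice`),
#'   each with `coefficients`, `fallback`, `n`.
#' @export
fitBehaviorModels <- function(trials) {
  if (is(trials, "ReachSession")) trials <- trialTable(trials)
  tr <- trials[trials$outcome != "aborted", ]
  tr$follow <- as.integer(tr$congruency == "follow")
  ins <- tr[tr$trial_type == "instructed", ]
  ins$err <- as.integer(ins$outcome == "error")
  fc <- tr[tr$trial_type == "free_choice", ]

  reports <- list(
    M1_error = fitOneModel(
      "M1_error", err ~ prior_level + prior_level:congruency,
      "(0 + prior_level:congruency | subject_id)", ins,
      family = binomial()),
    M1_rt = fitOneModel(
      "M1_rt", rt ~ prior_level + prior_level:congruency,
      "(0 + prior_level:congruency | subject_id)", tr),
    M2_choice = fitOneModel(
      "M2_choice", follow ~ prior_level,
      "(prior_level | subject_id)", fc, family = binomial())
  )
  reports
}

#' Bonferroni-corrected comparisons of successive prior levels
#'
#' For each behavioral measure and congruency, t-tests (two-sample on the
#' per-trial values; two-proportion for error/choice) between each pair
#' of neighboring prior levels, Bonferroni-corrected for the number of
#' neighbor pairs. Significance families at 5%, 1% and 0.1% are reported
#' as asterisk counts.
#'
#' @param trials completed trials data.frame (or [ReachSession-class]).
#' @return data.frame of contrasts: measure, congruency, levels compared,
#'   raw and corrected p, `stars`.
#' @export
posthocSuccessive <- function(trials) {
  if (is(trials, "ReachSession")) trials <- trialTable(trials)
  tr <- trials[trials$outcome != "aborted", ]
  rows <- list()
  addRow <- function(measure, cong, la, lb, p, k) {
    pb <- min(1, p * k)
    rows[[length(rows) + 1L]] <<- data.frame(
      measure = measure, congruency = cong, level_a = la, level_b = lb,
      p_raw = p, p_bonf = pb,
      stars = if (!is.finite(pb)) "" else
        if (pb < 0.001) "***" else if (pb < 0.01) "**"
        else if (pb < 0.05) "*" else "",
      stringsAsFactors = FALSE)
  }
  propTest <- function(x1, n1, x2, n2) {
    if (n1 == 0 || n2 == 0) return(NA_real_)
    if (x1 * n2 == x2 * n1) return(1)  # identical proportions
    suppressWarnings(stats::prop.test(c(x1, x2), c(n1, n2))$p.value)
  }
  ins <- tr[tr$trial_type == "instructed", ]
  for (cong in unique(ins$congruency)) {
    d <- ins[ins$congruency == cong, ]
    levs <- sort(unique(d$prior_level))
    k <- max(1L, length(levs) - 1L)
    for (i in seq_len(length(levs) - 1L)) {
      a <- d[d$prior_level == levs[i], ]
      b <- d[d$prior_level == levs[i + 1], ]
      p <- propTest(sum(a$outcome == "error"), nrow(a),
                    sum(b$outcome == "error"), nrow(b))
      addRow("error_rate", cong, levs[i], levs[i + 1], p, k)
      p <- if (nrow(a) > 1 && nrow(b) > 1 &&
               (sd(a$rt) > 0 || sd(b$rt) > 0))
        t.test(a$rt, b$rt)$p.value else 1
      addRow("rt", cong, levs[i], levs[i + 1], p, k)
    }
  }
  fc <- tr[tr$trial_type == "free_choice", ]
  levs <- sort(unique(fc$prior_level))
  k <- max(1L, length(levs) - 1L)
  for (i in seq_len(max(0L, length(levs) - 1L))) {
    a <- fc[fc$prior_level == levs[i], ]
    b <- fc[fc$prior_level == levs[i + 1], ]
    p <- propTest(sum(a$congruency == "follow"), nrow(a),
                  sum(b$congruency == "follow"), nrow(b))
    addRow("choice_probability", "all", levs[i], levs[i + 1], p, k)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
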