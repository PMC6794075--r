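#' Derive the normalized prior level from a likelihood ratio
#'
#' The pre-cue announces a likelihood ratio k:(6 - k) (ccw:cw) for which of
#' the two rotation rules will later be instructed. Each 8-trial block holds
#' six instructed trials (probability k/6 of instructing ccw, reward 1 unit)
#' and two free-choice trials (either rule valid, expected reward 1 unit at
#' probability 1/2 per rule). The initial expected value (iEV) of a rule
#' over a block is therefore
#' \deqn{iEV(k) = (6/8) (k/6) + (2/8) (1/2) = k/8 + 1/8,}
#' giving the iEV pairs {0.875:0.125, 0.75:0.25, 0.625:0.375, 0.5:0.5} for
#' the seven ratios. The prior level is the absolute normalized difference
#' of the two iEVs, |iEV_hi - iEV_lo| / (iEV_hi + iEV_lo), which takes the
#' four values {0, 0.25, 0.5, 0.75}.
#'
#' @param ratio integer vector of length 2, `c(ccw, cw)`, non-negative and
#'   summing to 6.
#' @return a list with elements `level` (numeric in {0, 0.25, 0.5, 0.75}),
#'   `high_prior_rule` (`"ccw"`, `"cw"` or `"tie"`), and `iev` (named
#'   numeric, the two initial expected values).
#' @examples
#' derivePriorLevel(c(6, 0)) # level 0.75, iEVs 0.875:0.125
#' derivePriorLevel(c(3, 3)) # level 0, tie
#' @export
derivePriorLevel <- function(ratio) {
  if (length(ratio) != 2L || anyNA(ratio) || !is.numeric(ratio) ||
      any(ratio < 0) || any(ratio != round(ratio)) || sum(ratio) != 6) {
    prStop("invalidRatioError",
           "prior ratio must be two non-negative integers summing to 6, got [%s]",
           paste(ratio, collapse = ", "))
  }
  iev <- ratio / 8 + 1 / 8
  names(iev) <- c("ccw", "cw")
  level <- abs(iev[[1]] - iev[[2]]) / (iev[[1]] + iev[[2]])
  rule <- if (ratio[1] > ratio[2]) "ccw" else if (ratio[1] < ratio[2]) "cw" else "tie"
  list(level = level, high_prior_rule = rule, iev = iev)
}

#' The seven block-wise prior ratios of the task
#'
#' @return a data.frame with one row per ratio: `ccw`, `cw`, `level`,
#'   `high_prior_rule`.
#' @examples
#' priorRatioTable()
#' @export
priorRatioTable <- function() {
  out <- do.call(rbind, lapply(6:0, function(k) {
    d <- derivePriorLevel(c(k, 6 - k))
    data.frame(ccw = k, cw = 6 - k, level = d$level,
               high_prior_rule = d$high_prior_rule,
               iev_ccw = d$iev[["ccw"]], iev_cw = d$iev[["cw"]])
  }))
  rownames(out) <- NULL
  out
}
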