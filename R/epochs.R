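#' Analysis epoch windows
#'
#' The four analysis windows, each anchored to a trial event and expressed
#' as a half-open interval [start, end) in ms relative to that event:
#' baseline = [-300, 0) before pre-cue onset, pre-cue = [0, 300) after
#' pre-cue onset, planning = [-300, 0) before rule-cue onset, movement =
#' [movement_on, movement_off).
#'
#' @return a data.frame with columns `name`, `anchor_event`, `offset_start`,
#'   `offset_end` (NA for the movement end, which is trial-specific).
#' @examples
#' epochWindows()
#' @export
epochWindows <- function() {
  data.frame(
    name = c("baseline", "precue", "planning", "movement"),
    anchor_event = c("precue_on", "precue_on", "rulecue_on", "movement_on"),
    offset_start = c(-300, 0, -300, 0),
    offset_end = c(0, 300, 0, NA),
    stringsAsFactors = FALSE
  )
}

# Resolve an epoch window to absolute [start, end) ms for one trial.
# `trial` is a one-row data.frame with t_<event> columns.
resolveWindow <- function(window, trial) {
  anchor_col <- paste0("t_", window$anchor_event)
  if (!anchor_col %in% names(trial) || is.na(trial[[anchor_col]])) {
    prStop("missingEventError", "trial %s lacks anchor event '%s'",
           as.character(trial$trial_id), window$anchor_event)
  }
  t0 <- trial[[anchor_col]]
  if (window$name == "movement") {
    if (is.na(trial$t_movement_off)) {
      prStop("missingEventError", "trial %s lacks movement_off",
             as.character(trial$trial_id))
    }
    c(start = t0, end = trial$t_movement_off)
  } else {
    c(start = t0 + window$offset_start, end = t0 + window$offset_end)
  }
}

#' Firing rate of one unit in an epoch window of one trial
#'
#' Counts spikes in the half-open window [start, end) and divides by the
#' window length in seconds. The half-open convention means a spike exactly
#' at the window end is excluded, so disjoint adjacent windows never double
#' count a spike.
#'
#' @param spikeTimes numeric vector of spike times (ms from trial start) of
#'   one unit in one trial.
#' @param window one row of [epochWindows()] (data.frame with `name`,
#'   `anchor_event`, `offset_start`, `offset_end`).
#' @param trial one-row data.frame of the trial, with `t_<event>` columns.
#' @return firing rate in Hz (spikes/s).
#' @examples
#' tr <- data.frame(trial_id = 1, t_precue_on = 1000, t_movement_off = NA)
#' w <- epochWindows()[1, ] # baseline
#' epochRate(c(750, 800, 999), w, tr) # 3 spikes in 300 ms -> 10 Hz
#' @export
epochRate <- function(spikeTimes, window, trial) {
  win <- resolveWindow(window, trial)
  len_s <- (win[["end"]] - win[["start"]]) / 1000
  if (!is.finite(len_s) || len_s <= 0) {
    prStop("missingEventError", "degenerate window [%s, %s)",
           win[["start"]], win[["end"]])
  }
  n <- sum(spikeTimes >= win[["start"]] & spikeTimes < win[["end"]])
  n / len_s
}
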