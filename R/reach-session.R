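#' ReachSession: a container for one dataset of the reach-selection task
#'
#' Bundles the three tables that describe a recorded or simulated dataset:
#' `units` (one row per unit: identity, area, optional `truth_*` columns for
#' synthetic ground truth), `trials` (one row per trial: pre-cue location,
#' prior ratio and level, trial type, rule, reach direction, congruency,
#' reaction time, outcome, and event times as `t_<event>` columns), and
#' `spikes` (unit_id, trial_id, time_ms). Validity enforces the data-model
#' invariants: resolvable foreign keys, event times strictly increasing in
#' task order, reaction time = movement onset - go and at most 800 ms for
#' completed trials, prior level consistent with the prior ratio, and reach
#' directions at the pre-cue location +/- 90 degrees.
#'
#' @slot units data.frame of unit records.
#' @slot trials data.frame of trial records.
#' @slot spikes data.frame of spike events.
#' @seealso [readDataset()], [writeDataset()], [simulateSession()]
#' @export
setClass("ReachSession",
         representation(units = "data.frame",
                        trials = "data.frame",
                        spikes = "data.frame"))

EVENT_COLUMNS <- paste0("t_", c("fixation_on", "precue_on", "precue_off",
                                "rulecue_on", "go", "movement_on",
                                "movement_off"))

UNIT_COLUMNS <- c("unit_id", "session_id", "subject_id", "area")
TRIAL_COLUMNS <- c("trial_id", "session_id", "subject_id", "precue_location",
                   "prior_ccw", "prior_cw", "prior_level", "trial_type",
                   "instructed_rule", "chosen_rule", "reach_direction",
                   "congruency", "rt", "outcome", EVENT_COLUMNS)
SPIKE_COLUMNS <- c("unit_id", "trial_id", "time_ms")

validReachSession <- function(object) {
  u <- object@units; tr <- object@trials; sp <- object@spikes
  bad <- function(fmt, ...) sprintf(fmt, ...)
  msgs <- character()

  miss <- setdiff(UNIT_COLUMNS, names(u))
  if (length(miss)) msgs <- c(msgs, bad("units lacks column(s): %s", toString(miss)))
  miss <- setdiff(TRIAL_COLUMNS, names(tr))
  if (length(miss)) msgs <- c(msgs, bad("trials lacks column(s): %s", toString(miss)))
  miss <- setdiff(SPIKE_COLUMNS, names(sp))
  if (length(miss)) msgs <- c(msgs, bad("spikes lacks column(s): %s", toString(miss)))
  if (length(msgs)) return(msgs)

  if (anyDuplicated(u$unit_id)) msgs <- c(msgs, "duplicated unit_id in units")
  if (anyDuplicated(tr$trial_id)) msgs <- c(msgs, "duplicated trial_id in trials")
  if (!all(u$area %in% c("PMd", "PRR")))
    msgs <- c(msgs, "area must be 'PMd' or 'PRR'")

  dangling <- setdiff(sp$unit_id, u$unit_id)
  if (length(dangling))
    msgs <- c(msgs, bad("spikes reference unknown unit_id: %s",
                        toString(head(dangling, 3))))
  dangling <- setdiff(sp$trial_id, tr$trial_id)
  if (length(dangling))
    msgs <- c(msgs, bad("spikes reference unknown trial_id: %s",
                        toString(head(dangling, 3))))

  if (nrow(tr)) {
    if (!all(tr$precue_location %in% CARDINAL_DIRECTIONS))
      msgs <- c(msgs, "precue_location must be one of 0, 90, 180, 270")
    if (!all(tr$trial_type %in% c("instructed", "free_choice")))
      msgs <- c(msgs, "trial_type must be 'instructed' or 'free_choice'")
    if (!all(tr$outcome %in% c("correct", "error", "aborted")))
      msgs <- c(msgs, "outcome must be correct/error/aborted")
    ratio_ok <- tr$prior_ccw >= 0 & tr$prior_cw >= 0 &
      (tr$prior_ccw + tr$prior_cw) == 6
    if (!all(ratio_ok))
      msgs <- c(msgs, bad("invalid prior ratio in trial row(s) %s",
                          toString(head(which(!ratio_ok), 3))))
    lev <- abs(tr$prior_ccw - tr$prior_cw) / 8
    if (any(abs(lev - tr$prior_level) > 1e-9))
      msgs <- c(msgs, "prior_level inconsistent with prior ratio")
    fc <- tr$trial_type == "free_choice"
    if (any(tr$instructed_rule[fc] != "none"))
      msgs <- c(msgs, "free-choice trials must have instructed_rule = 'none'")
    has_reach <- !is.na(tr$reach_direction)
    if (any(has_reach &
            angleDistance(tr$reach_direction, tr$precue_location) != 90))
      msgs <- c(msgs, "reach_direction must be precue_location +/- 90 deg")

    ev <- as.matrix(tr[, EVENT_COLUMNS])
    done <- tr$outcome != "aborted"
    if (any(done)) {
      evd <- ev[done, , drop = FALSE]
      if (anyNA(evd)) {
        msgs <- c(msgs, "completed trials must have all event times")
      } else {
        nondec <- apply(evd, 1L, function(z) all(diff(z) >= 0))
        # strict increase except go may coincide with rule-cue onset
        strict <- apply(evd[, setdiff(EVENT_COLUMNS, "t_go"), drop = FALSE],
                        1L, function(z) all(diff(z) > 0))
        if (!all(nondec & strict)) {
          i <- which(!(nondec & strict))[1]
          msgs <- c(msgs, bad("non-monotone event times in trial %s",
                              as.character(tr$trial_id[done][i])))
        }
        rt <- evd[, "t_movement_on"] - evd[, "t_go"]
        if (any(abs(rt - tr$rt[done]) > 1e-6))
          msgs <- c(msgs, "rt must equal movement_on - go")
        if (any(rt > 800))
          msgs <- c(msgs, "rt exceeds the 800 ms response limit")
      }
    }
  }
  if (nrow(sp) && any(sp$time_ms < 0))
    msgs <- c(msgs, "spike times must be >= 0")

  if (length(msgs)) msgs else TRUE
}

setValidity("ReachSession", validReachSession)

#' Construct a ReachSession
#'
#' @param units,trials,spikes data.frames; see [ReachSession-class] for the
#'   required columns.
#' @return a validated `ReachSession`.
#' @export
ReachSession <- function(units, trials, spikes) {
  new("ReachSession", units = units, trials = trials, spikes = spikes)
}

#' @describeIn ReachSession-class number of units.
#' @param object,x a `ReachSession`.
#' @export
setMethod("length", "ReachSession", function(x) nrow(x@units))

setMethod("show", "ReachSession", function(object) {
  u <- object@units
  cat("ReachSession with", nrow(u), "units,",
      nrow(object@trials), "trials,",
      nrow(object@spikes), "spikes\n")
  if (nrow(u)) {
    cat("  areas:", paste(sprintf("%s (%d)", names(table(u$area)),
                                  as.integer(table(u$area))),
                          collapse = ", "), "\n")
    cat("  sessions:", length(unique(u$session_id)),
        " subjects:", length(unique(u$subject_id)), "\n")
  }
  if (nrow(object@trials)) {
    tt <- table(object@trials$trial_type)
    cat("  trial types:", paste(sprintf("%s (%d)", names(tt),
                                        as.integer(tt)), collapse = ", "),
        "\n")
  }
})

#' @rdname accessors
#' @name accessors
#' @title Table accessors for ReachSession
#' @param session a [ReachSession-class].
#' @return the requested data.frame.
NULL

#' @rdname accessors
#' @export
unitTable <- function(session) session@units

#' @rdname accessors
#' @export
trialTable <- function(session) session@trials

#' @rdname accessors
#' @export
spikeTable <- function(session) session@spikes

#' Read a dataset bundle from CSV files
#'
#' Expects `units.csv`, `trials.csv` and `spikes.csv` under `dir` (or
#' explicit paths). All ReachSession invariants are validated; violations
#' raise a schema-validation error naming the offending row.
#'
#' @param dir directory holding the three CSVs.
#' @param unitsFile,trialsFile,spikesFile explicit paths (override `dir`).
#' @return a [ReachSession-class].
#' @export
readDataset <- function(dir = ".",
                        unitsFile = file.path(dir, "units.csv"),
                        trialsFile = file.path(dir, "trials.csv"),
                        spikesFile = file.path(dir, "spikes.csv")) {
  for (f in c(unitsFile, trialsFile, spikesFile)) {
    if (!file.exists(f))
      prStop("schemaValidationError", "missing input file: %s", f)
  }
  units <- read.csv(unitsFile, stringsAsFactors = FALSE)
  trials <- read.csv(trialsFile, stringsAsFactors = FALSE)
  spikes <- read.csv(spikesFile, stringsAsFactors = FALSE)
  if (!nrow(spikes))
    spikes <- data.frame(unit_id = character(), trial_id = character(),
                         time_ms = numeric(), stringsAsFactors = FALSE)
  spikes$unit_id <- as.character(spikes$unit_id)
  spikes$trial_id <- as.character(spikes$trial_id)
  units$unit_id <- as.character(units$unit_id)
  trials$trial_id <- as.character(trials$trial_id)
  tryCatch(ReachSession(units, trials, spikes),
           error = function(e) prStop("schemaValidationError", "%s",
                                      conditionMessage(e)))
}

#' Write a dataset bundle to CSV files
#'
#' Inverse of [readDataset()]; a written dataset reads back identically.
#'
#' @param session a [ReachSession-class].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
writeDataset <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(session@units, file.path(dir, "units.csv"), row.names = FALSE)
  write.csv(session@trials, file.path(dir, "trials.csv"), row.names = FALSE)
  write.csv(session@spikes, file.path(dir, "spikes.csv"), row.names = FALSE)
  invisible(dir)
}
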