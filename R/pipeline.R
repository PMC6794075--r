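#' Run the full analysis pipeline on a synthetic session
#'
#' Executes simulate -> behavior -> tuning -> classify -> latency -> roc
#' in dependency order, writes every stage's tables under `outDir`, and
#' emits a markdown report together with a JSON run manifest (config
#' snapshot, child seeds, per-stage counts and wall-clock, output file
#' digests). The report asserts the qualitative population findings the
#' synthetic conditions encode: graded upregulation at PD_max in UR
#' neurons, graded downregulation at OD in DR neurons, no orthogonal
#' modulation, bimodality of the modulation-angle distribution, and the
#' configured PMd-DR-first selection-latency ordering.
#'
#' @param config configuration overrides (see [validateConfig()]).
#' @param seed integer root seed.
#' @param outDir output directory.
#' @return invisibly, a list with `manifest`, `assertions`, and the main
#'   stage results.
#' @export
runPipeline <- function(config = list(), seed = 1, outDir = "pipeline_out") {
  cfg <- validateConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  t_start <- Sys.time()
  stages <- list()
  timed <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      prStop("pipelineStageError", "stage '%s' failed: %s", name,
             conditionMessage(e)))
    stages[[name]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    res
  }

  session <- timed("simulate", simulateSession(cfg, seed))
  writeDataset(session, file.path(outDir, "dataset"))

  behavior <- timed("behavior", {
    list(summary = summarizeBehavior(session),
         models = fitBehaviorModels(session),
         posthoc = posthocSuccessive(session))
  })
  write.csv(behavior$summary$conditions,
            file.path(outDir, "behavior_conditions.csv"),
            row.names = FALSE)
  write.csv(behavior$summary$choice,
            file.path(outDir, "behavior_choice.csv"), row.names = FALSE)

  gating <- timed("tuning", gateMotorGoalUnits(session, cfg))
  write.csv(gating, file.path(outDir, "unit_tuning.csv"),
            row.names = FALSE)
  poptun <- timed("population_tuning", populationTuning(session, gating))
  write.csv(poptun, file.path(outDir, "population_tuning.csv"),
            row.names = FALSE)

  classes <- timed("classify",
                   classifyUnits(session, gating, cfg,
                                 seed = childSeed(seed, "classify")))
  write.csv(classes, file.path(outDir, "unit_modulation.csv"),
            row.names = FALSE)
  un <- unitTable(session)
  popmod <- timed("population_modulation", {
    lapply(split(classes$unit_id, list(classes$area, classes$klass)),
           function(ids) if (length(ids) >= 3)
             populationModulationTest(session, gating, units = ids)
           else NULL)
  })

  latency <- timed("latency",
                   latencySuite(session, gating, classes, cfg, seed))

  roc <- timed("roc", choiceRocSuite(session, gating, cfg))
  if (!is.null(roc$roc))
    write.csv(roc$roc, file.path(outDir, "choice_roc.csv"),
              row.names = FALSE)
  correl <- timed("correlations", signalCorrelations(session, gating))
  if (!is.null(correl$pairs))
    write.csv(correl$pairs, file.path(outDir, "signal_correlations.csv"),
              row.names = FALSE)

  assertions <- pipelineAssertions(popmod, classes, latency)
  report <- renderReport(session, behavior, gating, classes, popmod,
                         latency, roc, correl, assertions)
  writeLines(report, file.path(outDir, "report.md"))

  files <- list.files(outDir, recursive = TRUE, full.names = TRUE)
  manifest <- list(
    config = cfg,
    seed = seed,
    child_seeds = sapply(c("units", "trials", "behavior", "spikes",
                           "classify", "latency"),
                         function(s) childSeed(seed, s)),
    counts = list(
      n_units = nrow(un),
      n_trials = nrow(trialTable(session)),
      n_spikes = nrow(spikeTable(session)),
      n_gated = sum(gating$gated),
      classes = as.list(table(classes$klass))),
    stage_seconds = stages,
    total_seconds = round(as.numeric(difftime(Sys.time(), t_start,
                                              units = "secs")), 2),
    files = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, assertions = assertions,
                 session = session, behavior = behavior, gating = gating,
                 classes = classes, population_modulation = popmod,
                 latency = latency, roc = roc,
                 correlations = correl))
}

#' Selection-latency suite per area and neuron class
#'
#' Neural-distance latency analysis for each area x class population
#' (classified UR/DR units) on the configured prior conditions:
#' point estimates (MVT/PT), unit-bootstrap CIs, and between-population
#' permutation tests (areas within class, classes within area).
#'
#' @param session a [ReachSession-class].
#' @param gating output of [gateMotorGoalUnits()].
#' @param classes output of [classifyUnits()].
#' @param cfg validated configuration.
#' @param seed integer seed for bootstrap/permutation child streams.
#' @return list with `groups` (per population: nd input, estimates,
#'   bootstrap) and `permutations` (pairwise tests).
#' @export
latencySuite <- function(session, gating, classes, cfg = list(),
                         seed = 1) {
  cfg <- validateConfig(cfg)
  levels_ <- vapply(cfg$analysis$latency_ratios,
                    function(r) derivePriorLevel(r)$level, numeric(1))
  un <- unitTable(session)
  groups <- list()
  for (area in c("PMd", "PRR")) for (kl in c("DR", "UR")) {
    ids <- classes$unit_id[classes$area == area & classes$klass == kl]
    if (length(ids) < 3) next
    nd_in <- tryCatch(
      neuralDistanceInput(session, gating, cfg, units = ids,
                          priorLevels = unique(levels_)),
      error = function(e) NULL)
    if (is.null(nd_in) || dim(nd_in$diff)[1] < 3 ||
        dim(nd_in$diff)[3] == 0) next
    est <- latencyEstimates(neuralDistance(nd_in),
                            window = cfg$analysis$mvt_window,
                            threshold = cfg$analysis$velocity_threshold)
    boot <- bootstrapND(nd_in, nBoot = cfg$analysis$n_boot,
                        seed = childSeed(seed, paste0("boot_", area, kl)),
                        window = cfg$analysis$mvt_window,
                        threshold = cfg$analysis$velocity_threshold)
    groups[[paste(area, kl, sep = "_")]] <-
      list(nd_input = nd_in, estimate = est, boot = boot,
           n_units = dim(nd_in$diff)[1])
  }
  perms <- list()
  pairsOf <- list(c("PMd_DR", "PRR_DR"), c("PMd_UR", "PRR_UR"),
                  c("PMd_DR", "PMd_UR"), c("PRR_DR", "PRR_UR"))
  for (pr in pairsOf) {
    if (all(pr %in% names(groups))) {
      perms[[paste(pr, collapse = "_vs_")]] <- permutationAreaTest(
        groups[[pr[1]]]$nd_input, groups[[pr[2]]]$nd_input,
        nPerm = cfg$analysis$n_perm,
        seed = childSeed(seed, paste0("perm_", paste(pr, collapse = ""))),
        window = cfg$analysis$mvt_window,
        threshold = cfg$analysis$velocity_threshold)
    }
  }
  list(groups = groups, permutations = perms,
       prior_levels = unique(levels_))
}

pipelineAssertions <- function(popmod, classes, latency) {
  getSlope <- function(grp, role) {
    pm <- popmod[[grp]]
    if (is.null(pm)) return(NULL)
    pm$slopes[pm$slopes$role == role, ]
  }
  sigPos <- function(s) !is.null(s) && nrow(s) && is.finite(s$p) &&
    s$p < 0.05 && s$mean_slope > 0
  sigNeg <- function(s) !is.null(s) && nrow(s) && is.finite(s$p) &&
    s$p < 0.05 && s$mean_slope < 0
  nullSlope <- function(s) is.null(s) || !nrow(s) || !is.finite(s$p) ||
    s$p >= 0.05
  ur_up <- vapply(c("PMd.UR", "PRR.UR"),
                  function(g) sigPos(getSlope(g, "PD_max")), logical(1))
  dr_down <- vapply(c("PMd.DR", "PRR.DR"),
                    function(g) sigNeg(getSlope(g, "OD")), logical(1))
  orth_null <- vapply(c("PMd.UR", "PRR.UR", "PMd.DR", "PRR.DR"),
                      function(g) nullSlope(getSlope(g, "Orth")),
                      logical(1))
  dips <- attr(classes, "dip")
  dip_ok <- vapply(dips, function(d) is.finite(d$p) && d$p < 0.05,
                   logical(1))
  mvts <- vapply(latency$groups, function(g)
    if (is.null(g$estimate$mvt)) NA_real_ else g$estimate$mvt,
    numeric(1))
  pmd_dr_first <- length(mvts) >= 2 && "PMd_DR" %in% names(mvts) &&
    all(mvts[["PMd_DR"]] <= mvts[setdiff(names(mvts), "PMd_DR")],
        na.rm = TRUE)
  list(ur_upregulation = all(ur_up),
       dr_downregulation = all(dr_down),
       no_orth_modulation = all(orth_null),
       angle_bimodality = all(dip_ok),
       pmd_dr_earliest = pmd_dr_first,
       mvt_ms = as.list(mvts))
}

renderReport <- function(session, behavior, gating, classes, popmod,
                         latency, roc, correl, assertions) {
  un <- unitTable(session)
  ch <- behavior$summary$choice
  counts <- attr(classes, "counts")
  dips <- attr(classes, "dip")
  fmtCheck <- function(x) if (isTRUE(x)) "PASS" else "FAIL"
  lines <- c(
    "# Synthetic reach-selection pipeline report", "",
    sprintf("Units: %d (%s); trials: %d; gated motor-goal neurons: %d",
            nrow(un),
            paste(sprintf("%s %d", names(table(un$area)),
                          as.integer(table(un$area))), collapse = ", "),
            nrow(trialTable(session)), sum(gating$gated)), "",
    "## Behavior", "",
    "Choice probability toward the high-prior goal by prior level:", "",
    paste(sprintf("- level %.2f: %.3f (n = %d)", ch$prior_level,
                  ch$choice_probability, ch$n), collapse = "\n"), "",
    "## Prior-modulation classes", "",
    paste(utils::capture.output(print(counts)), collapse = "\n"), "",
    paste(sprintf("- %s: dip = %.4f, p = %.4g",
                  names(dips),
                  vapply(dips, `[[`, numeric(1), "dip"),
                  vapply(dips, `[[`, numeric(1), "p")),
          collapse = "\n"), "",
    "## Selection-signal latencies (MVT, ms after rule-cue)", "",
    if (length(latency$groups))
      paste(sprintf("- %s: MVT = %.0f ms [%.0f, %.0f] (n = %d units)",
                    names(latency$groups),
                    vapply(latency$groups,
                           function(g) g$estimate$mvt, numeric(1)),
                    vapply(latency$groups,
                           function(g) g$boot$mvt_ci[1], numeric(1)),
                    vapply(latency$groups,
                           function(g) g$boot$mvt_ci[2], numeric(1)),
                    vapply(latency$groups,
                           function(g) g$n_units, numeric(1))),
            collapse = "\n")
    else "- no latency groups with enough units", "",
    "## Assertions", "",
    sprintf("- graded PD_max upregulation in UR neurons: %s",
            fmtCheck(assertions$ur_upregulation)),
    sprintf("- graded OD downregulation in DR neurons: %s",
            fmtCheck(assertions$dr_downregulation)),
    sprintf("- no orthogonal-direction prior modulation: %s",
            fmtCheck(assertions$no_orth_modulation)),
    sprintf("- bimodal modulation-angle distribution: %s",
            fmtCheck(assertions$angle_bimodality)),
    sprintf("- PMd-DR earliest selection signal: %s",
            fmtCheck(assertions$pmd_dr_earliest)))
  if (!is.null(roc$summary)) {
    lines <- c(lines, "", "## Choice-predictive ROC (pooled)", "",
               paste(sprintf("- %s: mean AUC = %.3f (n = %d units)",
                             roc$summary$comparison, roc$summary$mean_auc,
                             roc$summary$n_units), collapse = "\n"))
  }
  lines
}
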