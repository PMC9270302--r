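#' @include io.R
NULL

logStage <- function(fmt, ...) {
  message(sprintf("[qvpullback] %s", sprintf(fmt, ...)))
}

tracePath <- function(outDir, vesselId, phase) {
  file.path(outDir, "traces",
            sprintf("%s_%s.tsv", vesselId,
                    if (phase == "pre_pci") "pre" else "post"))
}

#' Pipeline stage: simulate a cohort and write it to disk
#'
#' Generates the synthetic cohort described by the configuration and writes
#' one TSV per trace under `<outDir>/traces/` plus a `manifest.json` linking
#' vessels to patients, traces, ground-truth patterns and PCI outcomes.
#'
#' @param config a [pipelineConfig()].
#' @param outDir output directory (created if needed).
#' @return The manifest as a data.frame, invisibly.
#' @export
stageSimulate <- function(config, outDir) {
  dir.create(file.path(outDir, "traces"), recursive = TRUE,
             showWarnings = FALSE)
  spec <- cohortSpecFromConfig(config)
  cohort <- generateCohort(spec,
                           strategy = config$pci$strategy,
                           maxStentMm = config$pci$maxStentMm,
                           instentLossPerMm = config$pci$instentLossPerMm)
  man <- cohortManifest(cohort)
  man$trace_pre <- file.path("traces", sprintf("%s_pre.tsv", man$vessel_id))
  man$trace_post <- file.path("traces", sprintf("%s_post.tsv", man$vessel_id))
  for (v in vessels(cohort)) {
    writeTrace(tracePre(v), tracePath(outDir, vesselId(v), "pre_pci"))
    writeTrace(tracePost(v), tracePath(outDir, vesselId(v), "post_pci"))
  }
  stented <- lapply(vessels(cohort), function(v) {
    s <- stentedIntervals(v)
    lapply(seq_len(nrow(s)), function(i) c(start = s[i, 1L], end = s[i, 2L]))
  })
  manifest <- list(spec = list(nVessels = spec@nVessels,
                               patternMix = as.list(spec@patternMix),
                               tvlRangeMm = spec@tvlRangeMm,
                               distalQfrRange = spec@distalQfrRange,
                               noiseSd = spec@noiseSd, seed = spec@seed,
                               multiVesselFrac = spec@multiVesselFrac,
                               stepMm = spec@stepMm),
                   vessels = cbind(man,
                                   data.frame(stents = I(stented))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logStage("simulate: %d vessels written to %s", nrow(man), outDir)
  invisible(man)
}

readManifest <- function(outDir) {
  path <- file.path(outDir, "manifest.json")
  qvpAssert(file.exists(path), "parseError", "no manifest.json in %s", outDir)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

loadManifestTraces <- function(outDir) {
  man <- readManifest(outDir)$vessels
  lapply(seq_len(nrow(man)), function(i) {
    prePath <- file.path(outDir, man$trace_pre[i])
    postPath <- file.path(outDir, man$trace_post[i])
    if (!file.exists(prePath) || !file.exists(postPath))
      qvpStop("parseError", "vessel %s: missing trace file (%s)",
              man$vessel_id[i],
              if (!file.exists(prePath)) prePath else postPath)
    list(vessel_id = man$vessel_id[i],
         patient_id = man$patient_id[i],
         true_pattern = man$true_pattern[i],
         pre = readTrace(prePath, man$vessel_id[i], "pre_pci"),
         post = readTrace(postPath, man$vessel_id[i], "post_pci"))
  })
}

#' Pipeline stage: score the quantitative method on a simulated cohort
#'
#' Reads every pre-PCI trace referenced by the manifest, computes the
#' quantitative metrics and QVP classification, and writes `metrics.csv`.
#'
#' @inheritParams stageSimulate
#' @return The metrics table, invisibly.
#' @export
stageScore <- function(config, outDir) {
  traces <- loadManifestTraces(outDir)
  th <- thresholdsFromConfig(config)
  rows <- lapply(traces, function(tr) {
    m <- vesselMetrics(tr$pre, stepMm = config$stepMm)
    postQ <- qfrValues(tr$post)[length(qfrValues(tr$post))]
    data.frame(vessel_id = tr$vessel_id, phase = "pre_pci",
               tvl_mm = m$tvlMm, distal_qfr = m$distalQfr,
               delta_qfr = m$deltaQfr, max20 = m$max20,
               lfd_mm = m$lfdMm, qvp_index = m$qvpIndex,
               qvp_predicted_pattern =
                 as.character(qvpPredictedPattern(m$qvpIndex, th)),
               qvp_tertile = as.character(qvpTertile(m$qvpIndex, th)),
               post_qfr = postQ,
               suboptimal = postQ <= th$suboptimalPostQfr,
               stringsAsFactors = FALSE)
  })
  metrics <- do.call(rbind, rows)
  utils::write.csv(metrics, file.path(outDir, "metrics.csv"),
                   row.names = FALSE)
  logStage("score: %d vessels -> metrics.csv", nrow(metrics))
  invisible(metrics)
}

#' Pipeline stage: qualitative classification of a simulated cohort
#'
#' Classifies each pre-PCI trace under the configured (strict) classifier and
#' the lenient preset, writing `patterns.csv` and the per-event companion
#' table `events.csv`.
#'
#' @inheritParams stageSimulate
#' @return The pattern table, invisibly.
#' @export
stageClassify <- function(config, outDir) {
  traces <- loadManifestTraces(outDir)
  cfg <- classifierConfigFromConfig(config)
  lenient <- classifierConfig("lenient")
  patRows <- list(); evRows <- list()
  for (tr in traces) {
    cls <- classifyVessel(tr$pre, cfg, config$stepMm)
    clsL <- classifyVessel(tr$pre, lenient, config$stepMm)
    patRows[[length(patRows) + 1L]] <-
      data.frame(vessel_id = tr$vessel_id,
                 pattern = as.character(cls$pattern),
                 pattern_lenient = as.character(clsL$pattern),
                 true_pattern = tr$true_pattern,
                 n_focal_drops = sum(cls$events$kind == "focal"),
                 n_diffuse_segments = sum(cls$events$kind == "diffuse"),
                 stringsAsFactors = FALSE)
    if (nrow(cls$events))
      evRows[[length(evRows) + 1L]] <-
        cbind(data.frame(vessel_id = tr$vessel_id), cls$events)
  }
  patterns <- do.call(rbind, patRows)
  events <- if (length(evRows)) do.call(rbind, evRows) else
    cbind(data.frame(vessel_id = character(0)), emptyDropEvents())
  utils::write.csv(patterns, file.path(outDir, "patterns.csv"),
                   row.names = FALSE)
  utils::write.csv(events, file.path(outDir, "events.csv"), row.names = FALSE)
  logStage("classify: %d vessels -> patterns.csv (%d events)",
           nrow(patterns), nrow(events))
  invisible(patterns)
}

#' Pipeline stage: cohort statistics report
#'
#' Joins `metrics.csv` and `patterns.csv`, runs [analyzeCohort()] and writes
#' `report.json` (all statistics with confidence intervals, seeds and a
#' configuration echo).
#'
#' @inheritParams stageSimulate
#' @return The analysis list, invisibly.
#' @export
stageAnalyze <- function(config, outDir) {
  metrics <- utils::read.csv(file.path(outDir, "metrics.csv"),
                             stringsAsFactors = FALSE)
  patterns <- utils::read.csv(file.path(outDir, "patterns.csv"),
                              stringsAsFactors = FALSE)
  man <- readManifest(outDir)$vessels
  scored <- merge(merge(metrics, patterns, by = "vessel_id"),
                  man[, c("vessel_id", "patient_id")], by = "vessel_id")
  res <- analyzeCohort(scored, thresholdsFromConfig(config),
                       mcReplicates = config$analysis$mcReplicates,
                       mcSeed = config$analysis$mcSeed)
  report <- c(list(config = unclass(config)), unclass(res))
  report$rocFocal <- report$rocFocal[c("auc", "optimalCutoff",
                                       "sensitivityAtOptimum",
                                       "specificityAtOptimum")]
  report$rocDiffuse <- report$rocDiffuse[c("auc", "optimalCutoff",
                                           "sensitivityAtOptimum",
                                           "specificityAtOptimum")]
  if (!is.null(report$rocSuboptimal))
    report$rocSuboptimal <- report$rocSuboptimal[c("auc", "optimalCutoff",
                                                   "sensitivityAtOptimum",
                                                   "specificityAtOptimum")]
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE, na = "null")
  logStage("analyze: report.json written")
  invisible(res)
}

#' Run the full pullback pipeline
#'
#' Chains simulate, score, classify and analyze, writing all outputs under
#' `outDir`. Identical configuration and seed give byte-identical output
#' files; timestamps appear only in log messages (stderr), never in data
#' files.
#'
#' @inheritParams stageSimulate
#' @return Named character vector of the written file paths, invisibly.
#' @export
runPipeline <- function(config, outDir) {
  stageSimulate(config, outDir)
  stageScore(config, outDir)
  stageClassify(config, outDir)
  stageAnalyze(config, outDir)
  invisible(c(manifest = file.path(outDir, "manifest.json"),
              metrics = file.path(outDir, "metrics.csv"),
              patterns = file.path(outDir, "patterns.csv"),
              events = file.path(outDir, "events.csv"),
              report = file.path(outDir, "report.json")))
}
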