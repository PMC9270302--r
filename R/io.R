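#' @include analyze.R
NULL

#' Read a pullback trace from a TSV file
#'
#' Expects a UTF-8 TSV with header `position_mm<TAB>qfr` and one sample per
#' row ('.' decimal separator). Vessel identity and phase are not stored in
#' the file; they are supplied by the caller (typically from the cohort
#' manifest or the filename). Malformed files raise a `parseError` naming the
#' offending line.
#'
#' @param path file path.
#' @param vesselId vessel identifier to attach.
#' @param phase `"pre_pci"` or `"post_pci"`.
#' @return A [PullbackTrace-class].
#' @export
readTrace <- function(path, vesselId = sub("\\.tsv$", "", basename(path)),
                      phase = "pre_pci") {
  qvpAssert(file.exists(path), "parseError", "no such trace file: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    qvpStop("parseError", "%s: empty file, no samples", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L || header[1L] != "position_mm" || header[2L] != "qfr")
    qvpStop("parseError",
            "%s: line 1: expected header 'position_mm\tqfr'", path)
  if (length(lines) < 2L)
    qvpStop("parseError", "%s: no samples", path)
  n <- length(lines) - 1L
  pos <- numeric(n); qfr <- numeric(n)
  for (i in seq_len(n)) {
    cells <- strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1L]]
    if (length(cells) < 2L)
      qvpStop("parseError", "%s: line %d: expected two tab-separated cells",
              path, i + 1L)
    p <- suppressWarnings(as.numeric(cells[1L]))
    q <- suppressWarnings(as.numeric(cells[2L]))
    if (is.na(p) || is.na(q))
      qvpStop("parseError", "%s: line %d: non-numeric cell", path, i + 1L)
    if (i > 1L && p <= pos[i - 1L])
      qvpStop("parseError",
              "%s: line %d: positions must be strictly increasing", path, i + 1L)
    pos[i] <- p; qfr[i] <- q
  }
  tryCatch(PullbackTrace(vesselId, pos, qfr, phase),
           error = function(e)
             qvpStop("parseError", "%s: invalid trace: %s", path,
                     conditionMessage(e)))
}

#' Write a pullback trace to a TSV file
#'
#' Positions and QFR values are written with six decimal places, making the
#' write/read round trip lossless to 1e-6.
#'
#' @param trace a [PullbackTrace-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeTrace <- function(trace, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("position_mm\tqfr", con)
  writeLines(sprintf("%.6f\t%.6f", trace@positions, trace@qfr), con)
  invisible(path)
}

configDefaults <- function() {
  list(schemaVersion = 1,
       stepMm = 0.5,
       classifier = unclass(classifierConfig())[
         setdiff(names(unclass(classifierConfig())), "preset")],
       thresholds = unclass(qvpThresholds()),
       cohort = list(nVessels = 120,
                     patternMix = c(focal = 0.43, serial_lesions = 0.17,
                                    diffuse = 0.12, combination = 0.28),
                     tvlRangeMm = c(55, 80),
                     distalQfrRange = c(0.70, 0.77),
                     noiseSd = 0.005,
                     seed = 1,
                     multiVesselFrac = 0.075,
                     stepMm = 0.5),
       pci = list(strategy = "stent-focal-components",
                  maxStentMm = 40,
                  instentLossPerMm = 0.0015),
       analysis = list(mcReplicates = 1e5, mcSeed = 20260923))
}

canonicalizeConfig <- function(cfg) {
  base <- configDefaults()
  mergeInto <- function(defaults, user) {
    for (k in names(user)) {
      defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]]))
        mergeInto(defaults[[k]], user[[k]]) else user[[k]]
    }
    defaults
  }
  cfg <- mergeInto(base, cfg)
  # YAML round-trips a named numeric vector as a map (list); re-flatten it
  cfg$cohort$patternMix <- unlist(cfg$cohort$patternMix)
  # numeric leaves as double, preserving names, so save/load is an identity
  normalize <- function(x) {
    if (is.list(x)) return(lapply(x, normalize))
    if (is.numeric(x)) return(stats::setNames(as.numeric(x), names(x)))
    x
  }
  cfg <- normalize(cfg)
  mixNames <- patternLevels()
  qvpAssert(length(cfg$cohort$patternMix) == 4L,
            "invalidParameter", "cohort patternMix must have four entries")
  names(cfg$cohort$patternMix) <- mixNames
  structure(cfg, class = "qvpPipelineConfig")
}

#' Pipeline configuration
#'
#' Builds the single configuration object of the pipeline: resampling step,
#' classifier thresholds, published QVP cutoffs, cohort-generation spec, PCI
#' simulation parameters and analysis seeds. Every published threshold is a
#' default here and never hard-coded at a call site. `writePipelineConfig()` /
#' `readPipelineConfig()` serialize it to YAML; loading a saved configuration
#' returns an identical object.
#'
#' @param ... named overrides of the defaults; nested sections
#'   (`classifier`, `thresholds`, `cohort`, `pci`, `analysis`) may be given
#'   as partial lists.
#' @return A list of class `qvpPipelineConfig`.
#' @export
pipelineConfig <- function(...) {
  canonicalizeConfig(list(...))
}

#' @rdname pipelineConfig
#' @param config a `qvpPipelineConfig`.
#' @param path YAML file path.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipelineConfig
#' @export
readPipelineConfig <- function(path) {
  qvpAssert(file.exists(path), "parseError", "no such config file: %s", path)
  canonicalizeConfig(yaml::read_yaml(path))
}

cohortSpecFromConfig <- function(config) {
  ch <- config$cohort
  cohortSpec(nVessels = ch$nVessels, patternMix = ch$patternMix,
             tvlRangeMm = ch$tvlRangeMm, distalQfrRange = ch$distalQfrRange,
             noiseSd = ch$noiseSd, seed = ch$seed,
             multiVesselFrac = ch$multiVesselFrac, stepMm = ch$stepMm)
}

classifierConfigFromConfig <- function(config) {
  do.call(classifierConfig, c(list(preset = "strict"), config$classifier))
}

thresholdsFromConfig <- function(config) {
  do.call(qvpThresholds, config$thresholds)
}
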