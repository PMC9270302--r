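#' @include qvp.R
NULL

#' Configuration of the qualitative pattern classifier
#'
#' Numeric quantification of the visual reading rules: a focal drop is a loss
#' of at least `focalMinDrop` QFR units within at most `focalMaxSpanMm` mm;
#' two focal drops count as separate when at least `separationMm` mm of
#' near-plateau (losing less than `plateauMaxDrop`) lies between them; a
#' diffuse decline is a diseased segment of at least `diffuseMinLenMm` mm
#' losing at least `diffuseMinDrop` in total after focal windows are excluded.
#'
#' Two presets emulate a two-reviewer workflow: `"strict"` (the defaults) and
#' `"lenient"`, which admits slightly smaller and closer drops and shorter
#' diffuse declines, the way a second human reader might.
#'
#' @param preset `"strict"` (default) or `"lenient"`.
#' @param focalMinDrop minimal focal drop (QFR units).
#' @param focalMaxSpanMm maximal focal drop span (mm).
#' @param diffuseMinLenMm minimal diffuse decline length (mm).
#' @param diffuseMinDrop minimal cumulative diffuse drop (QFR units).
#' @param separationMm minimal plateau between separate focal drops (mm).
#' @param plateauMaxDrop maximal QFR loss across a separating plateau.
#' @param coreSpanMm,coreMinDrop a focal window must contain a steep core: at
#'   least `coreMinDrop` lost over some `coreSpanMm`-mm sub-interval (windows
#'   narrower than `coreSpanMm` qualify outright). This operationalizes the
#'   "clear evidence of a focal drop" that distinguishes a step-up from a
#'   noisy stretch of progressive decline, whose loss over `coreSpanMm` stays
#'   well below this bound.
#' @param slopeEps,mergeGapMm segmentation parameters, see
#'   [functionalDiseaseLength()].
#' @return A list of class `classifierConfig`.
#' @export
classifierConfig <- function(preset = c("strict", "lenient"),
                             focalMinDrop = NULL, focalMaxSpanMm = NULL,
                             diffuseMinLenMm = NULL, diffuseMinDrop = NULL,
                             separationMm = NULL, plateauMaxDrop = NULL,
                             coreSpanMm = NULL, coreMinDrop = NULL,
                             slopeEps = NULL, mergeGapMm = NULL) {
  preset <- match.arg(preset)
  base <- list(focalMinDrop = 0.05, focalMaxSpanMm = 10,
               diffuseMinLenMm = 15, diffuseMinDrop = 0.05,
               separationMm = 5, plateauMaxDrop = 0.01,
               coreSpanMm = 4, coreMinDrop = 0.03,
               slopeEps = 0.002, mergeGapMm = 4)
  if (preset == "lenient") {
    base$focalMinDrop <- 0.045
    base$diffuseMinLenMm <- 12
    base$separationMm <- 4
    base$plateauMaxDrop <- 0.015
    base$coreMinDrop <- 0.025
  }
  user <- list(focalMinDrop = focalMinDrop, focalMaxSpanMm = focalMaxSpanMm,
               diffuseMinLenMm = diffuseMinLenMm, diffuseMinDrop = diffuseMinDrop,
               separationMm = separationMm, plateauMaxDrop = plateauMaxDrop,
               coreSpanMm = coreSpanMm, coreMinDrop = coreMinDrop,
               slopeEps = slopeEps, mergeGapMm = mergeGapMm)
  for (k in names(user)) if (!is.null(user[[k]])) base[[k]] <- user[[k]]
  qvpAssert(base$focalMinDrop > 0 && base$focalMaxSpanMm > 0 &&
              base$diffuseMinLenMm > 0 && base$separationMm >= 0,
            "invalidParameter", "classifier thresholds must be positive")
  structure(c(base, list(preset = preset)), class = "classifierConfig")
}

emptyDropEvents <- function() {
  data.frame(startMm = numeric(0), endMm = numeric(0),
             magnitude = numeric(0), kind = character(0),
             stringsAsFactors = FALSE)
}

# Shrink [i, j] (grid indices) so it does not start or end on an exactly flat
# cell; the monotone envelope produces exact plateaus, so this trims window
# padding without changing the captured drop.
trimFlat <- function(q, i, j) {
  while (i < j && q[i] - q[i + 1L] <= 0) i <- i + 1L
  while (j > i && q[j - 1L] - q[j] <= 0) j <- j - 1L
  c(i, j)
}

#' Detect focal drops and diffuse declines in a pullback trace
#'
#' Focal events are found by scanning every grid window no wider than
#' `focalMaxSpanMm` for a QFR loss of at least `focalMinDrop` containing a
#' steep core (see [classifierConfig()]); candidates are
#' accepted greedily by descending magnitude (preferring tighter windows, then
#' smaller start positions) and a new candidate is rejected when it overlaps
#' an accepted event or is not separated from it by at least `separationMm`
#' of near-plateau. Diffuse events are the merged diseased segments (see
#' [functionalDiseaseLength()]) that, after removal of the focal windows,
#' remain at least `diffuseMinLenMm` long and lose at least `diffuseMinDrop`.
#'
#' @param trace a pre-processed [PullbackTrace-class] (see
#'   [preprocessTrace()]).
#' @param config a [classifierConfig()] list.
#' @return A data.frame of events sorted by `startMm` with columns `startMm`,
#'   `endMm`, `magnitude`, `kind` (`"focal"` or `"diffuse"`); empty for a
#'   disease-free vessel.
#' @export
detectDrops <- function(trace, config = classifierConfig()) {
  p <- trace@positions; q <- trace@qfr
  n <- length(p)
  tvl <- p[n]

  # QFR lost over a core-span sub-window starting at each grid point
  coreDrop <- q - interpQfr(p, q, pmin(p + config$coreSpanMm, tvl))
  coreEnd <- p + config$coreSpanMm

  # enumerate candidate focal windows on the grid; a window qualifies when it
  # loses focalMinDrop and contains a steep core (or is narrower than one)
  cand <- list()
  for (i in seq_len(n - 1L)) {
    jmax <- i
    while (jmax < n && p[jmax + 1L] - p[i] <= config$focalMaxSpanMm + 1e-9)
      jmax <- jmax + 1L
    if (jmax == i) next
    js <- (i + 1L):jmax
    drops <- q[i] - q[js]
    ok <- which(drops >= config$focalMinDrop - 1e-12)
    for (k in ok) {
      j <- js[k]
      hasCore <- p[j] - p[i] <= config$coreSpanMm + 1e-9 ||
        any(coreDrop[i:j][coreEnd[i:j] <= p[j] + 1e-9] >=
              config$coreMinDrop - 1e-12)
      if (hasCore)
        cand[[length(cand) + 1L]] <- c(i, j, drops[k])
    }
  }

  selected <- list()
  if (length(cand)) {
    cm <- do.call(rbind, cand)
    span <- p[cm[, 2L]] - p[cm[, 1L]]
    ord <- order(-cm[, 3L], span, p[cm[, 1L]])
    cm <- cm[ord, , drop = FALSE]
    for (r in seq_len(nrow(cm))) {
      cs <- p[cm[r, 1L]]; ce <- p[cm[r, 2L]]
      ok <- TRUE
      for (s in selected) {
        if (cs < s["endMm"] && s["startMm"] < ce) { ok <- FALSE; break }
        gapLo <- min(ce, s["endMm"]); gapHi <- max(cs, s["startMm"])
        gapDrop <- interpQfr(p, q, gapLo) - interpQfr(p, q, gapHi)
        if (gapHi - gapLo < config$separationMm ||
            gapDrop >= config$plateauMaxDrop) { ok <- FALSE; break }
      }
      if (ok) {
        ij <- trimFlat(q, cm[r, 1L], cm[r, 2L])
        selected[[length(selected) + 1L]] <-
          c(startMm = p[ij[1L]], endMm = p[ij[2L]],
            magnitude = q[ij[1L]] - q[ij[2L]])
      }
    }
  }

  focal <- if (length(selected)) {
    fm <- as.data.frame(do.call(rbind, selected))
    fm$kind <- "focal"
    fm
  } else emptyDropEvents()

  # diffuse declines: diseased segments minus the focal windows
  segs <- functionalDiseaseLength(trace, config$slopeEps, config$mergeGapMm)$segments
  fIv <- if (nrow(focal)) cbind(focal$startMm, focal$endMm) else NULL
  rest <- subtractIntervals(segs, fIv)
  diffuse <- emptyDropEvents()
  if (nrow(rest)) {
    len <- rest[, 2L] - rest[, 1L]
    mag <- interpQfr(p, q, rest[, 1L]) - interpQfr(p, q, rest[, 2L])
    keep <- len >= config$diffuseMinLenMm - 1e-9 &
      mag >= config$diffuseMinDrop - 1e-12
    if (any(keep))
      diffuse <- data.frame(startMm = rest[keep, 1L], endMm = rest[keep, 2L],
                            magnitude = mag[keep], kind = "diffuse",
                            stringsAsFactors = FALSE)
  }

  out <- rbind(focal, diffuse)
  out <- out[order(out$startMm), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify the functional pattern of CAD from detected drop events
#'
#' Applies the reading rules: exactly one focal drop and no diffuse decline is
#' a focal pattern; two or more separated focal drops are serial lesions; a
#' progressive decline without focal drop is diffuse disease; any mixture of
#' focal and diffuse events is a combination. A vessel with no events has no
#' functional disease and raises an error of class `noFunctionalDisease`.
#'
#' @param drops event data.frame from [detectDrops()].
#' @return A single factor with levels `focal`, `serial_lesions`, `diffuse`,
#'   `combination`.
#' @export
classifyPattern <- function(drops) {
  nF <- sum(drops$kind == "focal")
  nD <- sum(drops$kind == "diffuse")
  if (nF + nD == 0L)
    qvpStop("noFunctionalDisease",
            "no drop events: vessel has no functional disease to classify")
  lab <- if (nF >= 1L && nD >= 1L) "combination"
  else if (nF == 1L) "focal"
  else if (nF >= 2L) "serial_lesions"
  else "diffuse"
  factor(lab, levels = patternLevels())
}

#' One-call qualitative classification of a raw trace
#'
#' Pre-processes the trace, detects events and classifies the pattern.
#'
#' @param trace a raw [PullbackTrace-class].
#' @param config a [classifierConfig()].
#' @param stepMm resampling step for pre-processing (mm).
#' @return A list with `pattern` (factor) and `events` (data.frame).
#' @export
classifyVessel <- function(trace, config = classifierConfig(), stepMm = 0.5) {
  tr <- preprocessTrace(trace, stepMm)
  ev <- detectDrops(tr, config)
  list(pattern = classifyPattern(ev), events = ev)
}
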