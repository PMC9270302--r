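#' @include trace-core.R
NULL

#' Published decision thresholds for the QVP index
#'
#' Container for the cutoffs used throughout the analysis, in QFR/QVP units:
#' QVP above `focalPredCutoff` predicts a focal pattern, at or below
#' `diffusePredCutoff` a diffuse pattern; QVP at or below
#' `suboptimalQvpCutoff` predicts a suboptimal PCI result; `tertileBounds`
#' split the QVP distribution into lowest / intermediate / highest tertiles;
#' a post-PCI QFR at or below `suboptimalPostQfr` defines the suboptimal PCI
#' endpoint. Boundary semantics follow the printed inequality signs exactly
#' (> 0.71, <= 0.51, <= 0.57, <= 0.54 / <= 0.71, <= 0.89).
#'
#' @param focalPredCutoff QVP above this predicts focal disease.
#' @param diffusePredCutoff QVP at or below this predicts diffuse disease.
#' @param suboptimalQvpCutoff QVP at or below this predicts suboptimal PCI.
#' @param tertileBounds two increasing bounds of the QVP tertiles.
#' @param suboptimalPostQfr post-PCI QFR defining a suboptimal result.
#' @return A list of class `qvpThresholds`.
#' @export
qvpThresholds <- function(focalPredCutoff = 0.71,
                          diffusePredCutoff = 0.51,
                          suboptimalQvpCutoff = 0.57,
                          tertileBounds = c(0.54, 0.71),
                          suboptimalPostQfr = 0.89) {
  qvpAssert(diffusePredCutoff < suboptimalQvpCutoff &&
              suboptimalQvpCutoff < focalPredCutoff,
            "invalidParameter",
            "cutoffs must satisfy diffuse < suboptimal < focal")
  qvpAssert(length(tertileBounds) == 2L && tertileBounds[1L] < tertileBounds[2L],
            "invalidParameter", "tertileBounds must be two increasing values")
  structure(list(focalPredCutoff = focalPredCutoff,
                 diffusePredCutoff = diffusePredCutoff,
                 suboptimalQvpCutoff = suboptimalQvpCutoff,
                 tertileBounds = as.numeric(tertileBounds),
                 suboptimalPostQfr = suboptimalPostQfr),
            class = "qvpThresholds")
}

#' Maximal QFR drop over a sliding window
#'
#' Scans every window of length `windowMm` that lies fully inside the vessel
#' and returns the largest QFR loss across a window, together with the window
#' start. Ties are broken towards the smallest start position. Vessels no
#' longer than the window return the whole-vessel gradient with start 0.
#'
#' @param trace a pre-processed [PullbackTrace-class] (see
#'   [preprocessTrace()]).
#' @param windowMm window length in mm (default 20).
#' @return A list with `drop` (QFR units) and `windowStartMm`.
#' @export
maxDropOverWindow <- function(trace, windowMm = 20) {
  qvpAssert(is.numeric(windowMm) && length(windowMm) == 1L && windowMm > 0,
            "invalidParameter", "windowMm must be a positive number")
  tvl <- totalVesselLength(trace)
  if (tvl <= windowMm + 1e-9)
    return(list(drop = deltaQFRVessel(trace), windowStartMm = 0))
  starts <- trace@positions[trace@positions <= tvl - windowMm + 1e-9]
  last <- tvl - windowMm
  if (last - starts[length(starts)] > 1e-9) starts <- c(starts, last)
  drops <- interpQfr(trace@positions, trace@qfr, starts) -
    interpQfr(trace@positions, trace@qfr, starts + windowMm)
  i <- which.max(drops)           # first max = smallest start
  list(drop = drops[i], windowStartMm = starts[i])
}

#' Length of vessel with functional disease
#'
#' Marks a grid cell as diseased when its local downward slope exceeds
#' `slopeEps` (QFR units per mm), then merges runs of diseased cells that are
#' separated by less than `mergeGapMm`. The length with functional disease
#' (LFD) is the total length of the merged segments; a merged segment spans
#' any short gaps inside it.
#'
#' @param trace a pre-processed [PullbackTrace-class].
#' @param slopeEps minimal downward slope counting as disease (QFR/mm).
#' @param mergeGapMm segments closer than this are merged (mm).
#' @return A list with `lfdMm` and `segments`, a 2-column matrix of
#'   half-open `[start, end)` intervals (mm), sorted and disjoint.
#' @export
functionalDiseaseLength <- function(trace, slopeEps = 0.002, mergeGapMm = 4) {
  p <- trace@positions; q <- trace@qfr
  n <- length(p)
  width <- diff(p)
  slope <- (q[-n] - q[-1L]) / width
  bad <- slope > slopeEps
  if (!any(bad)) {
    return(list(lfdMm = 0,
                segments = matrix(numeric(0), ncol = 2L,
                                  dimnames = list(NULL, c("start", "end")))))
  }
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  segs <- cbind(start = p[starts[keep]], end = p[ends[keep] + 1L])
  segs <- mergeIntervals(segs, gapMm = mergeGapMm)
  list(lfdMm = sum(segs[, 2L] - segs[, 1L]), segments = segs)
}

#' QVP index from its components
#'
#' Combines the maximal 20-mm drop, the vessel gradient, and the diseased
#' fraction of the vessel into the QVP index:
#' `[(max20 / delta) + (1 - LFD / TVL)] / 2`. Values near 1 indicate focal
#' disease; values near 0 diffuse disease. The index is undefined for vessels
#' without functional disease (vessel gradient at or below `minDelta`), in
#' which case an error of class `noFunctionalDisease` is raised.
#'
#' @param metrics a list or one-row data.frame with fields `deltaQfr`,
#'   `max20`, `lfdMm`, `tvlMm` (e.g. from [vesselMetrics()]).
#' @param minDelta smallest vessel gradient considered diseased.
#' @return The QVP index, a value in `[0, 1]` on monotone traces.
#' @examples
#' computeQVPIndex(list(deltaQfr = 0.25, max20 = 0.25, lfdMm = 10, tvlMm = 80))
#' @export
computeQVPIndex <- function(metrics, minDelta = 0.02) {
  need <- c("deltaQfr", "max20", "lfdMm", "tvlMm")
  qvpAssert(all(need %in% names(metrics)), "invalidParameter",
            "metrics must provide deltaQfr, max20, lfdMm and tvlMm")
  d <- metrics[["deltaQfr"]]
  if (!is.finite(d) || d <= minDelta)
    qvpStop("noFunctionalDisease",
            "vessel gradient %.4f <= %.3f: QVP index undefined for a vessel without functional disease",
            d, minDelta)
  (metrics[["max20"]] / d + (1 - metrics[["lfdMm"]] / metrics[["tvlMm"]])) / 2
}

#' Quantitative-method metrics for one vessel
#'
#' Pre-processes the trace (uniform resampling plus monotone envelope) and
#' extracts all terms of the quantitative method - vessel gradient, maximal
#' drop over `windowMm`, length with functional disease, total vessel length,
#' distal QFR - together with the resulting QVP index.
#'
#' @param trace a [PullbackTrace-class] (raw; pre-processing is applied
#'   internally unless `preprocess = FALSE`).
#' @param stepMm resampling step (mm).
#' @param windowMm sliding-window length for the maximal drop (mm).
#' @param slopeEps,mergeGapMm see [functionalDiseaseLength()].
#' @param minDelta see [computeQVPIndex()].
#' @param preprocess set `FALSE` if `trace` is already pre-processed.
#' @return A one-row data.frame: `vesselId`, `phase`, `tvlMm`, `distalQfr`,
#'   `deltaQfr`, `max20`, `max20StartMm`, `lfdMm`, `qvpIndex`.
#' @export
vesselMetrics <- function(trace, stepMm = 0.5, windowMm = 20,
                          slopeEps = 0.002, mergeGapMm = 4, minDelta = 0.02,
                          preprocess = TRUE) {
  tr <- if (preprocess) preprocessTrace(trace, stepMm) else trace
  delta <- deltaQFRVessel(tr)
  mx <- maxDropOverWindow(tr, windowMm)
  fd <- functionalDiseaseLength(tr, slopeEps, mergeGapMm)
  m <- data.frame(vesselId = vesselId(tr), phase = phase(tr),
                  tvlMm = totalVesselLength(tr),
                  distalQfr = qfrValues(tr)[length(qfrValues(tr))],
                  deltaQfr = delta, max20 = mx$drop,
                  max20StartMm = mx$windowStartMm,
                  lfdMm = fd$lfdMm, stringsAsFactors = FALSE)
  m$qvpIndex <- computeQVPIndex(m, minDelta = minDelta)
  m
}

#' Pattern predicted from the QVP index
#'
#' Maps QVP values to the predicted pattern: above the focal cutoff (default
#' 0.71) predicts focal disease, at or below the diffuse cutoff (default 0.51)
#' predicts diffuse disease, anything between is intermediate.
#'
#' @param qvp QVP index value(s) in `[0, 1]`.
#' @param thresholds a [qvpThresholds()] object.
#' @return Factor with levels `focal_predicted`, `intermediate`,
#'   `diffuse_predicted`.
#' @export
qvpPredictedPattern <- function(qvp, thresholds = qvpThresholds()) {
  qvpAssert(all(is.finite(qvp)) && all(qvp >= 0) && all(qvp <= 1),
            "invalidParameter", "QVP index values must lie in [0, 1]")
  out <- ifelse(qvp > thresholds$focalPredCutoff, "focal_predicted",
                ifelse(qvp <= thresholds$diffusePredCutoff,
                       "diffuse_predicted", "intermediate"))
  factor(out, levels = c("focal_predicted", "intermediate", "diffuse_predicted"))
}

#' QVP tertile
#'
#' Assigns QVP values to the published tertiles: lowest (at or below the first
#' bound, default 0.54), intermediate (up to the second bound, default 0.71),
#' highest (above it).
#'
#' @inheritParams qvpPredictedPattern
#' @return Factor with levels `lowest`, `intermediate`, `highest`.
#' @export
qvpTertile <- function(qvp, thresholds = qvpThresholds()) {
  qvpAssert(all(is.finite(qvp)) && all(qvp >= 0) && all(qvp <= 1),
            "invalidParameter", "QVP index values must lie in [0, 1]")
  b <- thresholds$tertileBounds
  out <- ifelse(qvp <= b[1L], "lowest",
                ifelse(qvp <= b[2L], "intermediate", "highest"))
  factor(out, levels = c("lowest", "intermediate", "highest"))
}
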