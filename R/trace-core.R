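#' @include AllClasses.R
NULL

interpQfr <- function(positions, qfr, x) {
  stats::approx(positions, qfr, xout = x, method = "linear", ties = "ordered")$y
}

#' Resample a pullback trace onto a uniform grid
#'
#' Linearly interpolates the trace onto a uniform grid from the ostium (0 mm)
#' to the distal landmark. The total vessel length is always kept as the last
#' grid point, so when it is not a multiple of `stepMm` the final cell is
#' shorter than `stepMm`.
#'
#' @param trace a [PullbackTrace-class].
#' @param stepMm grid step in mm; must be positive and no longer than the
#'   vessel.
#' @return A resampled [PullbackTrace-class].
#' @examples
#' tr <- PullbackTrace("V001", c(0, 80), c(1.00, 0.75))
#' qfrValues(resampleTrace(tr, 20))   # 1.00 0.9375 0.875 0.8125 0.75
#' @export
setMethod("resampleTrace", "PullbackTrace", function(trace, stepMm) {
  tvl <- totalVesselLength(trace)
  qvpAssert(is.numeric(stepMm) && length(stepMm) == 1L && is.finite(stepMm) &&
              stepMm > 0 && stepMm <= tvl,
            "invalidParameter",
            "stepMm must be in (0, %g] mm", tvl)
  grid <- seq(0, tvl, by = stepMm)
  if (tvl - grid[length(grid)] > 1e-9) grid <- c(grid, tvl)
  grid[length(grid)] <- tvl   # exact, no accumulation error
  PullbackTrace(vesselId(trace), grid,
                interpQfr(trace@positions, trace@qfr, grid), phase(trace))
})

#' Non-increasing (isotonic) envelope of a pullback trace
#'
#' Replaces the QFR values by their least-squares non-increasing projection
#' (pool-adjacent-violators). A physiological pullback can only lose pressure
#' from ostium to distal vessel, so upward excursions are measurement noise;
#' the projection is order-preserving, parameter-free and idempotent, and all
#' downstream drop/decline metrics are defined on the projected trace.
#'
#' @param trace a [PullbackTrace-class].
#' @return A [PullbackTrace-class] with non-increasing QFR values.
#' @export
setMethod("monotoneEnvelope", "PullbackTrace", function(trace) {
  fit <- -stats::isoreg(trace@positions, -trace@qfr)$yf
  PullbackTrace(vesselId(trace), trace@positions, fit, phase(trace))
})

#' Index QFR: the QFR value at a single position
#'
#' The "index QFR" is the QFR read at one chosen cursor position along the
#' vessel; between samples it is obtained by linear interpolation.
#'
#' @param trace a [PullbackTrace-class].
#' @param positionMm position(s) in mm; must lie in `[0, TVL]`.
#' @return Numeric QFR value(s).
#' @export
setMethod("indexQFR", "PullbackTrace", function(trace, positionMm) {
  tvl <- totalVesselLength(trace)
  qvpAssert(is.numeric(positionMm) && all(is.finite(positionMm)) &&
              all(positionMm >= -1e-9) && all(positionMm <= tvl + 1e-9),
            "outOfRange",
            "position must lie within [0, %g] mm", tvl)
  interpQfr(trace@positions, trace@qfr, pmin(pmax(positionMm, 0), tvl))
})

#' Vessel-level QFR gradient (ostium minus distal)
#'
#' The difference between the QFR at the ostium and at the most distal
#' analysed location. On a raw noisy trace this can be marginally negative;
#' a warning is raised because drop metrics assume the monotone envelope has
#' been applied first.
#'
#' @param trace a [PullbackTrace-class].
#' @return A single numeric value (QFR units).
#' @export
setMethod("deltaQFRVessel", "PullbackTrace", function(trace) {
  d <- trace@qfr[1L] - trace@qfr[length(trace@qfr)]
  if (d < -1e-9)
    warning("negative vessel gradient on a non-monotone trace; ",
            "apply monotoneEnvelope() before computing drop metrics")
  d
})

#' Standard pre-processing for drop metrics
#'
#' Resamples the trace on a uniform grid (default 0.5 mm) and applies the
#' non-increasing envelope. All quantitative and qualitative drop metrics in
#' this package operate on the pre-processed trace.
#'
#' @param trace a [PullbackTrace-class].
#' @param stepMm resampling step in mm.
#' @return A pre-processed [PullbackTrace-class].
#' @export
preprocessTrace <- function(trace, stepMm = 0.5) {
  monotoneEnvelope(resampleTrace(trace, stepMm))
}
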