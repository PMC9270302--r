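#' @include classify.R
NULL

# Build a trace from an ostial QFR and lesion components on a uniform grid.
# Focal components are logistic steps (scaleMm sets the transition width);
# diffuse components are linear ramps over [startMm, endMm).
buildTraceFromComponents <- function(ostialQfr, components, tvlMm, stepMm,
                                     noiseSd, vesselId, phase) {
  x <- seq(0, tvlMm, by = stepMm)
  if (tvlMm - x[length(x)] > 1e-9) x <- c(x, tvlMm)
  q <- rep(ostialQfr, length(x))
  for (i in seq_len(nrow(components))) {
    cmp <- components[i, ]
    if (cmp$dropQfr <= 0) next
    if (cmp$kind == "focal") {
      q <- q - cmp$dropQfr * stats::plogis((x - cmp$centerMm) / cmp$scaleMm)
    } else {
      frac <- pmin(1, pmax(0, (x - cmp$startMm) / (cmp$endMm - cmp$startMm)))
      q <- q - cmp$dropQfr * frac
    }
  }
  if (noiseSd > 0) q <- q + stats::rnorm(length(x), 0, noiseSd)
  PullbackTrace(vesselId, x, pmin(pmax(q, 0.01), 1.05), phase)
}

componentRow <- function(kind, startMm, endMm, dropQfr,
                         centerMm = NA_real_, scaleMm = NA_real_) {
  data.frame(kind = kind, startMm = startMm, endMm = endMm,
             centerMm = centerMm, dropQfr = dropQfr, scaleMm = scaleMm,
             stringsAsFactors = FALSE)
}

focalComponent <- function(centerMm, dropQfr, scaleMm) {
  componentRow("focal", centerMm - 7, centerMm + 7, dropQfr, centerMm, scaleMm)
}

runifIn <- function(lo, hi, what) {
  if (lo > hi + 1e-12)
    qvpStop("generationError",
            "infeasible parameter combination while drawing %s (empty range [%.3f, %.3f])",
            what, lo, hi)
  stats::runif(1L, lo, min(lo + max(hi - lo, 0), hi))
}

# Per-pattern archetype draws. Each returns list(tvl, q0, components) whose
# zero-noise trace satisfies the generating pattern's reading rules by
# construction. A linear decline only stays "diffuse" if its steepest 10-mm
# drop stays clearly below the 0.05 focal threshold; the generator caps the
# ramp slope at 0.0041 QFR/mm (10-mm drop <= 0.041), which with a distal QFR
# target of 0.70-0.77 forces diffuse archetypes onto the longer vessels of the
# cohort range.
drawFocal <- function(spec) {
  tvl <- runifIn(spec@tvlRangeMm[1L], spec@tvlRangeMm[2L], "focal TVL")
  q0 <- stats::runif(1L, 0.972, 1.0)
  dt <- runifIn(spec@distalQfrRange[1L], spec@distalQfrRange[2L], "focal distal QFR")
  ctr <- runifIn(15, tvl - 18, "focal center")
  list(tvl = tvl, q0 = q0,
       components = focalComponent(ctr, q0 - dt, stats::runif(1L, 1.0, 1.6)))
}

drawSerial <- function(spec) {
  tvl <- runifIn(max(spec@tvlRangeMm[1L], 52), spec@tvlRangeMm[2L], "serial TVL")
  q0 <- stats::runif(1L, 0.972, 1.0)
  dt <- runifIn(spec@distalQfrRange[1L],
                min(0.75, spec@distalQfrRange[2L]), "serial distal QFR")
  D <- q0 - dt
  r <- stats::runif(1L, 0.55, 0.65)
  drops <- c(r, 1 - r) * D
  if (stats::runif(1L) < 0.5) drops <- rev(drops)
  c1 <- runifIn(12, min(18, tvl - 40), "first serial center")
  gap <- runifIn(25, min(35, tvl - 15 - c1), "serial center spacing")
  comps <- rbind(focalComponent(c1, drops[1L], stats::runif(1L, 1.0, 1.4)),
                 focalComponent(c1 + gap, drops[2L], stats::runif(1L, 1.0, 1.4)))
  list(tvl = tvl, q0 = q0, components = comps)
}

drawDiffuse <- function(spec) {
  maxSlope <- 0.0041                       # keeps any 10-mm drop <= 0.041
  q0 <- stats::runif(1L, 0.972, 1.0)
  dHi <- spec@distalQfrRange[2L]
  tvlLo <- max(spec@tvlRangeMm[1L], 14 + (q0 - dHi) / maxSlope + 0.5)
  tvl <- runifIn(tvlLo, spec@tvlRangeMm[2L], "diffuse TVL")
  D <- runifIn(q0 - dHi,
               min(q0 - spec@distalQfrRange[1L], maxSlope * (tvl - 14)),
               "diffuse total drop")
  ext <- runifIn(D / maxSlope, min(D / 0.0036, tvl - 14), "diffuse extent")
  st <- runifIn(6, tvl - 8 - ext, "diffuse start")
  list(tvl = tvl, q0 = q0,
       components = componentRow("diffuse", st, st + ext, D))
}

drawCombination <- function(spec) {
  tvl <- runifIn(max(spec@tvlRangeMm[1L], 64), spec@tvlRangeMm[2L],
                 "combination TVL")
  q0 <- stats::runif(1L, 0.972, 1.0)
  ext <- runifIn(26, min(36, tvl - 36), "combination diffuse extent")
  d <- ext * stats::runif(1L, 0.0038, 0.0041)
  f <- runifIn(max(0.085, q0 - spec@distalQfrRange[2L] - d),
               min(0.17, q0 - spec@distalQfrRange[1L] - d),
               "combination focal drop")
  s <- stats::runif(1L, 1.0, 1.4)
  if (stats::runif(1L) < 0.5) {           # focal proximal, ramp distal
    ctr <- runifIn(10, 14, "combination focal center")
    rs <- runifIn(ctr + 13, tvl - 8 - ext, "combination ramp start")
  } else {                                # ramp proximal, focal distal
    rs <- runifIn(6, 9, "combination ramp start")
    ctr <- runifIn(rs + ext + 13, tvl - 10, "combination focal center")
  }
  comps <- rbind(focalComponent(ctr, f, s),
                 componentRow("diffuse", rs, rs + ext, d))
  list(tvl = tvl, q0 = q0, components = comps)
}

#' Generate one synthetic vessel with known ground truth
#'
#' Draws lesion components for the requested functional pattern so that the
#' zero-noise trace satisfies that pattern's reading rules by construction
#' (focal drops are logistic steps with a 1-1.6 mm transition scale; diffuse
#' declines are linear ramps whose steepest 10-mm drop stays below the focal
#' threshold), builds the noisy pre-PCI trace, and simulates PCI.
#'
#' @param pattern one of `"focal"`, `"serial_lesions"`, `"diffuse"`,
#'   `"combination"`.
#' @param spec a [cohortSpec()] (its seed is ignored here; `seed` governs this
#'   vessel).
#' @param seed integer seed for this vessel; identical seeds give bit-identical
#'   vessels.
#' @param vesselId,patientId identifiers.
#' @param pci run [simulatePCI()] on the vessel (default TRUE).
#' @param strategy,maxStentMm,instentLossPerMm,instentEventProb,instentEventDropRange
#'   passed to [simulatePCI()].
#' @return A [SyntheticVessel-class].
#' @export
generateVessel <- function(pattern, spec, seed, vesselId = "V001",
                           patientId = vesselId, pci = TRUE,
                           strategy = "stent-focal-components",
                           maxStentMm = 40, instentLossPerMm = 0.0015,
                           instentEventProb = 0.12,
                           instentEventDropRange = c(0.03, 0.13)) {
  pattern <- match.arg(pattern, patternLevels())
  withSeed(seed, {
    arch <- switch(pattern,
                   focal = drawFocal(spec),
                   serial_lesions = drawSerial(spec),
                   diffuse = drawDiffuse(spec),
                   combination = drawCombination(spec))
    if (sum(arch$components$dropQfr) >= arch$q0 - 0.05)
      qvpStop("generationError",
              "requested drops (%.2f) exceed the ostial QFR headroom",
              sum(arch$components$dropQfr))
    tracePre <- buildTraceFromComponents(arch$q0, arch$components, arch$tvl,
                                         spec@stepMm, spec@noiseSd,
                                         vesselId, "pre_pci")
    v <- new("SyntheticVessel", vesselId = as.character(vesselId),
             patientId = as.character(patientId), tracePre = tracePre,
             tracePost = NULL, components = arch$components,
             truePattern = pattern, ostialQfr = arch$q0,
             postQfr = NA_real_,
             stentedIntervals = matrix(numeric(0), ncol = 2L,
                                       dimnames = list(NULL, c("start", "end"))))
    if (pci)
      v <- simulatePCI(v, strategy = strategy, maxStentMm = maxStentMm,
                       instentLossPerMm = instentLossPerMm,
                       instentEventProb = instentEventProb,
                       instentEventDropRange = instentEventDropRange,
                       noiseSd = spec@noiseSd, stepMm = spec@stepMm)
    v
  })
}

#' Simulate PCI on a synthetic vessel
#'
#' Chooses stented intervals, removes the drop of every lesion component fully
#' covered by a stent, reduces a partially covered component's drop in
#' proportion to the covered length (a partially covered ramp keeps its
#' residual gradient on the uncovered portions), adds in-stent pressure
#' losses, and rebuilds the post-PCI trace from the residual components with
#' fresh noise.
#'
#' Strategies: `"stent-focal-components"` stents each focal component (plus,
#' within the remaining stent budget, a central portion of the largest diffuse
#' component - the whole diffuse area never fits a stent);
#' `"stent-max-drop-segment"` places one stent over the maximal-drop window.
#'
#' In-stent losses have two parts: a small uniform loss per stented
#' millimetre, and - with probability `instentEventProb` per stent - a
#' focal in-stent drop, emulating the occasional residual in-stent gradient
#' that leaves even a well-covered lesion with a low post-PCI QFR (so vessels
#' needing more stents carry proportionally more risk). Total
#' in-stent loss is always capped below the drop the stents removed, so
#' simulated PCI never leaves the vessel worse than before.
#'
#' Randomness (stent length within its range, in-stent losses, trace noise)
#' is drawn from the current RNG stream; [generateVessel()] and
#' [generateCohort()] call this inside their seeded blocks.
#'
#' @param vessel a [SyntheticVessel-class] with at least one component.
#' @param strategy stenting strategy (see Details).
#' @param maxStentMm total stent budget in mm.
#' @param instentLossPerMm upper bound of the uniform in-stent QFR loss rate
#'   (QFR units per stented mm); 0 disables in-stent losses.
#' @param instentEventProb probability of a focal in-stent drop per stent;
#'   0 disables the mechanism.
#' @param instentEventDropRange uniform range of the in-stent drop magnitude.
#' @param noiseSd noise SD of the rebuilt post-PCI trace.
#' @param stepMm sampling step of the rebuilt trace.
#' @return The vessel with `tracePost`, `postQfr` and `stentedIntervals`
#'   filled in.
#' @export
simulatePCI <- function(vessel,
                        strategy = c("stent-focal-components",
                                     "stent-max-drop-segment"),
                        maxStentMm = 40, instentLossPerMm = 0.0015,
                        instentEventProb = 0.12,
                        instentEventDropRange = c(0.03, 0.13),
                        noiseSd = 0.005, stepMm = 0.5) {
  strategy <- match.arg(strategy)
  qvpAssert(maxStentMm > 0, "invalidParameter", "maxStentMm must be positive")
  comps <- vessel@components
  qvpAssert(nrow(comps) >= 1L, "invalidInput",
            "vessel has no lesion components")
  tvl <- totalVesselLength(vessel@tracePre)

  stents <- NULL
  if (strategy == "stent-focal-components") {
    budget <- maxStentMm
    foc <- comps[comps$kind == "focal", , drop = FALSE]
    if (nrow(foc)) {
      for (i in order(-foc$dropQfr)) {
        st <- c(max(0, foc$startMm[i] - 1), min(tvl, foc$endMm[i] + 1))
        if (st[2L] - st[1L] <= budget + 1e-9) {
          stents <- rbind(stents, st)
          budget <- budget - (st[2L] - st[1L])
        }
      }
    }
    dif <- comps[comps$kind == "diffuse", , drop = FALSE]
    if (nrow(dif) && budget >= 12) {
      i <- which.max(dif$dropQfr)
      extLen <- dif$endMm[i] - dif$startMm[i]
      lenRange <- if (nrow(foc)) c(12, 22) else c(26, 38)
      L <- min(budget, stats::runif(1L, lenRange[1L], lenRange[2L]), extLen)
      mid <- (dif$startMm[i] + dif$endMm[i]) / 2
      stents <- rbind(stents, c(max(0, mid - L / 2), min(tvl, mid + L / 2)))
    }
  } else {
    L <- min(maxStentMm, 30)
    mx <- maxDropOverWindow(preprocessTrace(vessel@tracePre, stepMm),
                            min(L, tvl))
    stents <- rbind(NULL, c(mx$windowStartMm,
                            min(tvl, mx$windowStartMm + L)))
  }
  colnames(stents) <- c("start", "end")
  rownames(stents) <- NULL

  residual <- comps[0, ]
  removedDrop <- 0
  for (i in seq_len(nrow(comps))) {
    cmp <- comps[i, ]
    len <- cmp$endMm - cmp$startMm
    cov <- coveredLength(cmp$startMm, cmp$endMm, stents) / len
    if (cov >= 1 - 1e-9) {                          # fully covered: removed
      removedDrop <- removedDrop + cmp$dropQfr
      next
    }
    if (cov <= 1e-9) { residual <- rbind(residual, cmp); next }
    removedDrop <- removedDrop + cmp$dropQfr * cov
    if (cmp$kind == "diffuse") {
      pieces <- subtractIntervals(cbind(cmp$startMm, cmp$endMm), stents)
      for (j in seq_len(nrow(pieces))) {
        pl <- pieces[j, 2L] - pieces[j, 1L]
        residual <- rbind(residual,
                          componentRow("diffuse", pieces[j, 1L], pieces[j, 2L],
                                       cmp$dropQfr * pl / len))
      }
    } else {
      cmp$dropQfr <- cmp$dropQfr * (1 - cov)        # partial focal coverage
      residual <- rbind(residual, cmp)
    }
  }

  # in-stent losses, capped below the removed drop: PCI never worsens a vessel
  losses <- comps[0, ]
  for (j in seq_len(nrow(stents))) {
    loss <- stats::runif(1L, 0, instentLossPerMm) *
      (stents[j, 2L] - stents[j, 1L])
    losses <- rbind(losses,
                    componentRow("diffuse", stents[j, 1L], stents[j, 2L], loss))
  }
  if (instentEventProb > 0) {
    for (j in seq_len(nrow(stents))) {
      if (stats::runif(1L) < instentEventProb)
        losses <- rbind(losses,
                        focalComponent((stents[j, 1L] + stents[j, 2L]) / 2,
                                       stats::runif(1L,
                                                    instentEventDropRange[1L],
                                                    instentEventDropRange[2L]),
                                       1))
    }
  }
  lossTotal <- sum(losses$dropQfr)
  lossCap <- max(0, removedDrop - 0.005)
  if (lossTotal > lossCap && lossTotal > 0)
    losses$dropQfr <- losses$dropQfr * (lossCap / lossTotal)
  residual <- rbind(residual, losses)
  if (nrow(residual) == 0L)
    residual <- componentRow("diffuse", 0, tvl, 0)   # disease-free post vessel

  tracePost <- buildTraceFromComponents(vessel@ostialQfr, residual, tvl,
                                        stepMm, noiseSd,
                                        vessel@vesselId, "post_pci")
  vessel@tracePost <- tracePost
  vessel@postQfr <- qfrValues(tracePost)[length(qfrValues(tracePost))]
  vessel@stentedIntervals <- stents
  vessel
}

#' Generate a synthetic pullback cohort
#'
#' Draws each vessel's pattern from the cohort specification's mixture, generates the
#' vessels (each from its own sub-seed of the cohort seed, so the cohort is
#' fully reproducible), assigns patients (optionally letting a fraction of
#' vessels share a patient), and runs [simulatePCI()] on every vessel.
#'
#' @param spec a [cohortSpec()].
#' @param strategy,maxStentMm,instentLossPerMm,instentEventProb,instentEventDropRange
#'   passed to [simulatePCI()].
#' @return A [PullbackCohort-class].
#' @export
generateCohort <- function(spec, strategy = "stent-focal-components",
                           maxStentMm = 40, instentLossPerMm = 0.0015,
                           instentEventProb = 0.12,
                           instentEventDropRange = c(0.03, 0.13)) {
  n <- spec@nVessels
  qvpAssert(n >= 1L, "invalidParameter", "nVessels must be >= 1")
  vesselList <- withSeed(spec@seed, {
    patterns <- sample(patternLevels(), n, replace = TRUE,
                       prob = spec@patternMix)
    seeds <- sample.int(2147483646L, n)
    patients <- sprintf("P%03d", seq_len(n))
    nShare <- round(spec@multiVesselFrac * n)
    if (nShare >= 1L && n >= 2L) {
      shared <- sample(2:n, min(nShare, n - 1L))
      for (i in shared)
        patients[i] <- patients[sample(setdiff(seq_len(n), shared), 1L)]
    }
    lapply(seq_len(n), function(i) {
      generateVessel(patterns[i], spec, seed = seeds[i],
                     vesselId = sprintf("V%03d", i), patientId = patients[i],
                     strategy = strategy, maxStentMm = maxStentMm,
                     instentLossPerMm = instentLossPerMm,
                     instentEventProb = instentEventProb,
                     instentEventDropRange = instentEventDropRange)
    })
  })
  new("PullbackCohort", vessels = vesselList, spec = spec)
}
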