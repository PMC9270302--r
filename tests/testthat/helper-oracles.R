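# Trace builders and independent brute-force oracles used across the suite.
# The oracles deliberately re-derive each quantity with naive loops so they
# share no code path with the package implementation.

linearTrace <- function(tvl, q0, q1, step = 0.5, id = "T", phase = "pre_pci") {
  x <- seq(0, tvl, by = step)
  if (tvl - x[length(x)] > 1e-9) x <- c(x, tvl)
  PullbackTrace(id, x, q0 + (q1 - q0) * x / tvl, phase)
}

# flat trace with linear ramps / logistic steps superimposed
compositeTrace <- function(tvl, q0, focal = NULL, ramps = NULL,
                           step = 0.5, noiseSd = 0, id = "T") {
  x <- seq(0, tvl, by = step)
  if (tvl - x[length(x)] > 1e-9) x <- c(x, tvl)
  q <- rep(q0, length(x))
  if (!is.null(focal)) {        # rows: center, drop, scale
    for (i in seq_len(nrow(focal)))
      q <- q - focal[i, 2] * plogis((x - focal[i, 1]) / focal[i, 3])
  }
  if (!is.null(ramps)) {        # rows: start, end, drop
    for (i in seq_len(nrow(ramps))) {
      frac <- pmin(1, pmax(0, (x - ramps[i, 1]) / (ramps[i, 2] - ramps[i, 1])))
      q <- q - ramps[i, 3] * frac
    }
  }
  if (noiseSd > 0) q <- q + rnorm(length(x), 0, noiseSd)
  PullbackTrace(id, x, pmin(pmax(q, 0.01), 1.05))
}

# random trace on a jittered (non-uniform) grid
jitteredTrace <- function(tvl = 60, n = 40, id = "J") {
  x <- sort(runif(n - 2, 0.5, tvl - 0.5))
  x <- c(0, x, tvl)
  q <- sort(runif(n, 0.7, 1.0), decreasing = TRUE)
  PullbackTrace(id, x, q)
}

# naive piecewise-linear interpolation, point by point
interpOracle <- function(pos, q, xout) {
  vapply(xout, function(x) {
    if (x <= pos[1]) return(q[1])
    if (x >= pos[length(pos)]) return(q[length(q)])
    i <- max(which(pos <= x))
    if (pos[i] == x) return(q[i])
    w <- (x - pos[i]) / (pos[i + 1] - pos[i])
    (1 - w) * q[i] + w * q[i + 1]
  }, numeric(1))
}

# exhaustive scan over every grid start position (plus the last feasible one)
maxDropOracle <- function(trace, windowMm) {
  p <- tracePositions(trace); q <- qfrValues(trace)
  tvl <- p[length(p)]
  if (tvl <= windowMm) {
    return(list(drop = q[1] - q[length(q)], start = 0))
  }
  starts <- p[p <= tvl - windowMm + 1e-9]
  if (tvl - windowMm - starts[length(starts)] > 1e-9)
    starts <- c(starts, tvl - windowMm)
  best <- -Inf; bestStart <- NA_real_
  for (s in starts) {
    d <- interpOracle(p, q, s) - interpOracle(p, q, s + windowMm)
    if (d > best + 1e-12) { best <- d; bestStart <- s }
  }
  list(drop = best, start = bestStart)
}

# direct per-cell thresholding plus interval merging
lfdOracle <- function(trace, slopeEps = 0.002, mergeGap = 4) {
  p <- tracePositions(trace); q <- qfrValues(trace)
  segs <- list(); cur <- NULL
  for (i in seq_len(length(p) - 1)) {
    diseased <- (q[i] - q[i + 1]) / (p[i + 1] - p[i]) > slopeEps
    if (diseased) {
      if (is.null(cur)) cur <- c(p[i], p[i + 1]) else cur[2] <- p[i + 1]
    } else if (!is.null(cur)) {
      segs[[length(segs) + 1]] <- cur; cur <- NULL
    }
  }
  if (!is.null(cur)) segs[[length(segs) + 1]] <- cur
  if (!length(segs)) return(list(lfd = 0, segments = NULL))
  merged <- list(segs[[1]])
  for (s in segs[-1]) {
    k <- length(merged)
    if (s[1] - merged[[k]][2] < mergeGap) merged[[k]][2] <- s[2]
    else merged[[length(merged) + 1]] <- s
  }
  m <- do.call(rbind, merged)
  list(lfd = sum(m[, 2] - m[, 1]), segments = m)
}

# independent re-implementation of the drop-detection predicates: enumerate
# candidate windows, greedy accept by magnitude (tighter, then more proximal,
# first), then diffuse remainders of the diseased segments
detectDropsOracle <- function(trace, cfg = classifierConfig()) {
  p <- tracePositions(trace); q <- qfrValues(trace)
  n <- length(p)
  tvl <- p[n]
  hasSteepCore <- function(i, j) {
    if (p[j] - p[i] <= cfg$coreSpanMm + 1e-9) return(TRUE)
    for (k in i:j) {
      if (p[k] + cfg$coreSpanMm > p[j] + 1e-9) next
      d <- q[k] - interpOracle(p, q, p[k] + cfg$coreSpanMm)
      if (d >= cfg$coreMinDrop - 1e-12) return(TRUE)
    }
    FALSE
  }
  cand <- NULL
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (p[j] - p[i] > cfg$focalMaxSpanMm + 1e-9) break
    if (q[i] - q[j] >= cfg$focalMinDrop - 1e-12 && hasSteepCore(i, j))
      cand <- rbind(cand, c(p[i], p[j], q[i] - q[j]))
  }
  sel <- NULL
  if (!is.null(cand)) {
    cand <- cand[order(-cand[, 3], cand[, 2] - cand[, 1], cand[, 1]), ,
                 drop = FALSE]
    for (r in seq_len(nrow(cand))) {
      cs <- cand[r, 1]; ce <- cand[r, 2]
      ok <- TRUE
      if (!is.null(sel)) for (k in seq_len(nrow(sel))) {
        ss <- sel[k, 1]; se <- sel[k, 2]
        if (cs < se && ss < ce) { ok <- FALSE; break }
        lo <- min(ce, se); hi <- max(cs, ss)
        gd <- interpOracle(p, q, lo) - interpOracle(p, q, hi)
        if (hi - lo < cfg$separationMm || gd >= cfg$plateauMaxDrop) {
          ok <- FALSE; break
        }
      }
      if (ok) {
        i <- which(p == cs); j <- which(p == ce)
        while (i < j && q[i] - q[i + 1] <= 0) i <- i + 1
        while (j > i && q[j - 1] - q[j] <= 0) j <- j - 1
        sel <- rbind(sel, c(p[i], p[j], q[i] - q[j]))
      }
    }
  }
  events <- NULL
  if (!is.null(sel))
    events <- data.frame(startMm = sel[, 1], endMm = sel[, 2],
                         magnitude = sel[, 3], kind = "focal")
  segs <- lfdOracle(trace, cfg$slopeEps, cfg$mergeGapMm)$segments
  if (!is.null(segs)) {
    for (i in seq_len(nrow(segs))) {
      pieces <- rbind(segs[i, , drop = FALSE])
      if (!is.null(sel)) for (k in seq_len(nrow(sel))) {
        nxt <- NULL
        for (r in seq_len(nrow(pieces))) {
          lo <- pieces[r, 1]; hi <- pieces[r, 2]
          if (sel[k, 2] <= lo || sel[k, 1] >= hi) { nxt <- rbind(nxt, c(lo, hi)); next }
          if (sel[k, 1] > lo) nxt <- rbind(nxt, c(lo, sel[k, 1]))
          if (sel[k, 2] < hi) nxt <- rbind(nxt, c(sel[k, 2], hi))
        }
        pieces <- nxt
        if (is.null(pieces)) break
      }
      if (!is.null(pieces)) for (r in seq_len(nrow(pieces))) {
        len <- pieces[r, 2] - pieces[r, 1]
        mag <- interpOracle(p, q, pieces[r, 1]) - interpOracle(p, q, pieces[r, 2])
        if (len >= cfg$diffuseMinLenMm - 1e-9 &&
            mag >= cfg$diffuseMinDrop - 1e-12)
          events <- rbind(events,
                          data.frame(startMm = pieces[r, 1], endMm = pieces[r, 2],
                                     magnitude = mag, kind = "diffuse"))
      }
    }
  }
  if (is.null(events)) return(NULL)
  events <- events[order(events$startMm), ]
  rownames(events) <- NULL
  events
}

# ROC by explicit threshold enumeration and AUC by pair counting
rocOracle <- function(scores, outcome, direction = "low") {
  outcome <- as.logical(outcome)
  ev <- scores[outcome]; ne <- scores[!outcome]
  conc <- 0
  for (a in ev) for (b in ne) {
    hit <- if (direction == "low") a < b else a > b
    conc <- conc + hit + 0.5 * (a == b)
  }
  auc <- conc / (length(ev) * length(ne))
  u <- sort(unique(scores))
  thr <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  bestJ <- -Inf; bestT <- NA_real_; bestSens <- NA; bestSpec <- NA
  for (t in thr) {
    if (direction == "low") {
      sens <- mean(ev <= t); spec <- mean(ne > t)
    } else {
      sens <- mean(ev >= t); spec <- mean(ne < t)
    }
    if (sens + spec > bestJ + 1e-12) {
      bestJ <- sens + spec; bestT <- t; bestSens <- sens; bestSpec <- spec
    }
  }
  list(auc = auc, cutoff = bestT, sens = bestSens, spec = bestSpec)
}

defaultSpec <- function(n = 10, seed = 1, noiseSd = 0.005, ...) {
  cohortSpec(nVessels = n, seed = seed, noiseSd = noiseSd, ...)
}
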