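# Internal helpers: classed error conditions, interval algebra, seeded evaluation.

qvpStop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "qvpullbackError")))
}

qvpAssert <- function(ok, class, fmt, ...) {
  if (!isTRUE(ok)) qvpStop(class, fmt, ...)
  invisible(TRUE)
}

# Merge sorted disjoint-ish intervals; intervals closer than gapMm (end-to-start)
# are fused into one. `m` is a 2-column matrix (start, end), rows sorted by start.
mergeIntervals <- function(m, gapMm = 0) {
  if (is.null(m) || nrow(m) == 0L) return(matrix(numeric(0), ncol = 2L,
                                                 dimnames = list(NULL, c("start", "end"))))
  m <- m[order(m[, 1L]), , drop = FALSE]
  out <- m[1L, , drop = FALSE]
  if (nrow(m) > 1L) {
    for (i in 2L:nrow(m)) {
      k <- nrow(out)
      if (m[i, 1L] - out[k, 2L] < gapMm) {
        out[k, 2L] <- max(out[k, 2L], m[i, 2L])
      } else {
        out <- rbind(out, m[i, , drop = FALSE])
      }
    }
  }
  colnames(out) <- c("start", "end")
  out
}

# Set difference a \ union(b) on half-open intervals; both 2-column matrices.
subtractIntervals <- function(a, b) {
  empty <- matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("start", "end")))
  if (is.null(a) || nrow(a) == 0L) return(empty)
  if (is.null(b) || nrow(b) == 0L) {
    colnames(a) <- c("start", "end")
    return(a)
  }
  b <- mergeIntervals(b)
  pieces <- list()
  for (i in seq_len(nrow(a))) {
    lo <- a[i, 1L]; hi <- a[i, 2L]
    for (j in seq_len(nrow(b))) {
      bs <- b[j, 1L]; be <- b[j, 2L]
      if (be <= lo || bs >= hi) next
      if (bs > lo) pieces[[length(pieces) + 1L]] <- c(lo, bs)
      lo <- max(lo, be)
      if (lo >= hi) break
    }
    if (lo < hi) pieces[[length(pieces) + 1L]] <- c(lo, hi)
  }
  if (length(pieces) == 0L) return(empty)
  out <- do.call(rbind, pieces)
  colnames(out) <- c("start", "end")
  out[order(out[, 1L]), , drop = FALSE]
}

# Total length covered by the intersection of interval [s, e) with the rows of m.
coveredLength <- function(s, e, m) {
  if (is.null(m) || nrow(m) == 0L) return(0)
  sum(pmax(0, pmin(e, m[, 2L]) - pmax(s, m[, 1L])))
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG stream afterwards.
withSeed <- function(seed, expr) {
  qvpAssert(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
            "invalidParameter", "seed must be a single finite number")
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hadSeed) oldSeed <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hadSeed) assign(".Random.seed", oldSeed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

patternLevels <- function() c("focal", "serial_lesions", "diffuse", "combination")
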