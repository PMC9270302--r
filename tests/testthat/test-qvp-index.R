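test_that("maximal windowed drop handles canonical shapes", {
  # uniform decline: every 20-mm window loses the same amount; start 0 reported
  lin <- linearTrace(100, 1.00, 0.75)
  mx <- maxDropOverWindow(lin, 20)
  expect_equal(mx$drop, 0.05)
  expect_equal(mx$windowStartMm, 0)

  # a single step is captured entirely by a window containing it
  stp <- compositeTrace(80, 1.0, focal = rbind(c(30, 0.25, 0.8)))
  mx <- maxDropOverWindow(monotoneEnvelope(stp), 20)
  expect_equal(mx$drop, 0.25, tolerance = 0.005)
  expect_true(mx$windowStartMm < 30 && mx$windowStartMm + 20 > 30)

  # short vessels fall back to the whole-vessel gradient
  short <- linearTrace(15, 1.0, 0.8)
  expect_equal(maxDropOverWindow(short, 20),
               list(drop = 0.2, windowStartMm = 0))

  expect_error(maxDropOverWindow(lin, 0), class = "invalidParameter")
  expect_error(maxDropOverWindow(lin, -3), class = "invalidParameter")
})

test_that("windowed drop equals the exhaustive scan on generated vessels", {
  withr::local_seed(31)
  spec <- defaultSpec(seed = 1)
  pats <- rep(patternLevels(), length.out = 40)
  for (k in seq_along(pats)) {
    v <- generateVessel(pats[k], spec, seed = 5000 + k, pci = FALSE)
    tr <- preprocessTrace(tracePre(v))
    got <- maxDropOverWindow(tr, 20)
    want <- maxDropOracle(tr, 20)
    expect_equal(got$drop, want$drop, tolerance = 1e-12)
    expect_equal(got$windowStartMm, want$start)
  }
})

test_that("functional-disease segmentation finds declining regions", {
  flat <- linearTrace(60, 0.95, 0.95)
  fd <- functionalDiseaseLength(flat)
  expect_equal(fd$lfdMm, 0)
  expect_equal(nrow(fd$segments), 0L)

  # decline confined to [20, 40): exactly that cell range is reported
  ramp <- compositeTrace(60, 1.0, ramps = rbind(c(20, 40, 0.2)))
  fd <- functionalDiseaseLength(ramp)
  expect_equal(fd$lfdMm, 20, tolerance = 0.5)
  expect_equal(nrow(fd$segments), 1L)
  expect_equal(unname(fd$segments[1, ]), c(20, 40), tolerance = 0.5)

  # nearby segments are merged across a sub-threshold gap
  two <- compositeTrace(60, 1.0,
                        ramps = rbind(c(10, 20, 0.1), c(23, 33, 0.1)))
  fd <- functionalDiseaseLength(two, mergeGapMm = 4)
  expect_equal(nrow(fd$segments), 1L)
  expect_equal(fd$lfdMm, 23, tolerance = 0.5)
})

test_that("segmentation equals the per-cell threshold oracle on noisy traces", {
  withr::local_seed(77)
  for (k in 1:40) {
    tr <- preprocessTrace(compositeTrace(
      70, 0.99,
      focal = rbind(c(runif(1, 15, 25), runif(1, 0.08, 0.2), runif(1, 1, 2))),
      ramps = rbind(c(40, 62, runif(1, 0.05, 0.12))),
      noiseSd = 0.005))
    got <- functionalDiseaseLength(tr)
    want <- lfdOracle(tr)
    expect_equal(got$lfdMm, want$lfd, tolerance = 1e-12)
    expect_equal(unname(got$segments), unname(want$segments))
  }
})

test_that("QVP index follows its closed forms exactly", {
  # all of the drop inside one window, short lesion
  expect_equal(computeQVPIndex(list(deltaQfr = 0.25, max20 = 0.25,
                                    lfdMm = 10, tvlMm = 80)),
               0.9375, tolerance = 1e-9)
  # full-length uniform decline: index collapses to 10 / TVL
  expect_equal(computeQVPIndex(list(deltaQfr = 0.25, max20 = 0.05,
                                    lfdMm = 100, tvlMm = 100)),
               0.10, tolerance = 1e-9)
  expect_equal(computeQVPIndex(list(deltaQfr = 0.4, max20 = 0.4 * 20 / 60,
                                    lfdMm = 60, tvlMm = 60)),
               10 / 60, tolerance = 1e-9)
  # disease-free vessels have no defined index
  expect_error(computeQVPIndex(list(deltaQfr = 0.01, max20 = 0.01,
                                    lfdMm = 0, tvlMm = 60)),
               class = "noFunctionalDisease")
})

test_that("compressing a short lesion raises the index through the LFD term", {
  # analytic value (1 + 1 - l/TVL)/2 for a lesion of length l <= 20
  tvl <- 80
  vals <- vapply(c(18, 12, 8, 4), function(l) {
    computeQVPIndex(list(deltaQfr = 0.25, max20 = 0.25, lfdMm = l, tvlMm = tvl))
  }, numeric(1))
  expect_equal(vals, (2 - c(18, 12, 8, 4) / tvl) / 2, tolerance = 1e-9)
  expect_true(all(diff(vals) > 0))
})

test_that("pipeline index equals hand evaluation from oracle components", {
  withr::local_seed(19)
  spec <- defaultSpec(seed = 1)
  for (k in 1:10) {
    v <- generateVessel(sample(patternLevels(), 1), spec, seed = 900 + k,
                        pci = FALSE)
    tr <- preprocessTrace(tracePre(v))
    m <- vesselMetrics(tracePre(v))
    byHand <- (maxDropOracle(tr, 20)$drop / deltaQFRVessel(tr) +
                 (1 - lfdOracle(tr)$lfd / totalVesselLength(tr))) / 2
    expect_equal(m$qvpIndex, byHand, tolerance = 1e-12)
    expect_gte(m$qvpIndex, 0)
    expect_lte(m$qvpIndex, 1)
    expect_lte(m$max20, m$deltaQfr + 1e-12)  # monotone trace bound
  }
})

test_that("QVP cutoffs and tertiles follow the printed inequality signs", {
  th <- qvpThresholds()
  expect_equal(as.character(qvpPredictedPattern(c(0.80, 0.38, 0.61), th)),
               c("focal_predicted", "diffuse_predicted", "intermediate"))
  # boundary semantics: > 0.71 focal, <= 0.51 diffuse
  expect_equal(as.character(qvpPredictedPattern(c(0.71, 0.7100001, 0.51, 0.512), th)),
               c("intermediate", "focal_predicted",
                 "diffuse_predicted", "intermediate"))
  expect_equal(as.character(qvpTertile(c(0.50, 0.54, 0.55, 0.71, 0.7101, 0.97), th)),
               c("lowest", "lowest", "intermediate", "intermediate",
                 "highest", "highest"))
  expect_error(qvpPredictedPattern(1.2, th), class = "invalidParameter")
  expect_error(qvpTertile(-0.1, th), class = "invalidParameter")
  expect_error(qvpThresholds(focalPredCutoff = 0.4), class = "invalidParameter")
})
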