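test_that("generation is deterministic given a seed", {
  spec <- defaultSpec(seed = 1)
  a <- generateVessel("focal", spec, seed = 42)
  b <- generateVessel("focal", spec, seed = 42)
  expect_identical(qfrValues(tracePre(a)), qfrValues(tracePre(b)))
  expect_identical(qfrValues(tracePost(a)), qfrValues(tracePost(b)))
  expect_identical(lesionComponents(a), lesionComponents(b))
  c <- generateVessel("focal", spec, seed = 43)
  expect_false(identical(qfrValues(tracePre(a)), qfrValues(tracePre(c))))
})

test_that("zero-noise archetypes satisfy their generating rules", {
  spec <- defaultSpec(seed = 1, noiseSd = 0)
  for (pat in patternLevels()) {
    for (k in 1:8) {
      v <- generateVessel(pat, spec, seed = 100 * k + match(pat, patternLevels()),
                          pci = FALSE)
      tr <- tracePre(v)
      q <- qfrValues(tr)
      expect_gte(q[1], 0.97 - 1e-6)
      expect_lte(q[1], 1.0)
      expect_true(all(diff(q) <= 1e-9))            # non-increasing before noise
      expect_gte(q[length(q)], spec@distalQfrRange[1] - 0.005)
      expect_lte(q[length(q)], spec@distalQfrRange[2] + 0.005)
      expect_equal(as.character(classifyVessel(tr)$pattern), pat)
    }
  }
})

test_that("diffuse archetypes expose their extent as functional-disease length", {
  spec <- defaultSpec(seed = 1, noiseSd = 0)
  for (k in 1:6) {
    v <- generateVessel("diffuse", spec, seed = 400 + k, pci = FALSE)
    cmp <- lesionComponents(v)
    ext <- cmp$endMm - cmp$startMm
    m <- vesselMetrics(tracePre(v))
    expect_equal(m$lfdMm, ext, tolerance = 0.1 * ext)
    expect_gt(m$lfdMm, 30)   # diffuse disease spans tens of millimetres
  }
})

test_that("stenting a focal-only vessel restores the trace", {
  spec <- defaultSpec(seed = 1, noiseSd = 0)
  v <- generateVessel("focal", spec, seed = 77, pci = FALSE)
  v <- withr::with_seed(1, simulatePCI(v, instentLossPerMm = 0,
                                       instentEventProb = 0, noiseSd = 0))
  expect_equal(postQFR(v), v@ostialQfr, tolerance = 0.005)
  expect_false(postQFR(v) <= qvpThresholds()$suboptimalPostQfr)
  expect_gt(sum(stentedIntervals(v)[, 2] - stentedIntervals(v)[, 1]), 0)
})

test_that("partial coverage of a ramp leaves a proportional residual", {
  # 0.20 drop over 45 mm; a 20-mm stent leaves 0.20 * 25/45 of the gradient
  comp <- data.frame(kind = "diffuse", startMm = 10, endMm = 55,
                     centerMm = NA_real_, dropQfr = 0.20, scaleMm = NA_real_)
  tr <- compositeTrace(65, 0.98, ramps = rbind(c(10, 55, 0.20)))
  v <- new("SyntheticVessel", vesselId = "H1", patientId = "H1",
           tracePre = tr, tracePost = NULL, components = comp,
           truePattern = "diffuse", ostialQfr = 0.98, postQfr = NA_real_,
           stentedIntervals = matrix(numeric(0), ncol = 2))
  v <- withr::with_seed(1,
    simulatePCI(v, strategy = "stent-max-drop-segment", maxStentMm = 20,
                instentLossPerMm = 0, instentEventProb = 0, noiseSd = 0))
  expect_equal(v@ostialQfr - postQFR(v), 0.20 * 25 / 45, tolerance = 0.01)
  expect_error(simulatePCI(v, maxStentMm = 0), class = "invalidParameter")
})

test_that("simulated PCI never worsens a vessel", {
  spec <- defaultSpec(seed = 1)
  withr::local_seed(9)
  for (k in 1:40) {
    v <- generateVessel(sample(patternLevels(), 1), spec, seed = 1300 + k)
    preDistal <- qfrValues(tracePre(v))[length(qfrValues(tracePre(v)))]
    expect_gte(postQFR(v), preDistal - 2 * spec@noiseSd)
  }
})

test_that("cohorts follow the requested mixture and reproduce bit-identically", {
  spec <- cohortSpec(nVessels = 120, seed = 2025)
  co <- generateCohort(spec)
  expect_equal(nVessels(co), 120L)
  counts <- table(factor(vapply(vessels(co), truePattern, character(1)),
                         levels = patternLevels()))
  expected <- 120 * c(0.43, 0.17, 0.12, 0.28)
  # realized counts within binomial 99.7% bounds of the target mixture
  for (i in 1:4) {
    sdL <- sqrt(expected[i] * (1 - expected[i] / 120))
    expect_lt(abs(counts[i] - expected[i]), 3.5 * sdL)
  }
  co2 <- generateCohort(spec)
  expect_identical(lapply(vessels(co), function(v) qfrValues(tracePre(v))),
                   lapply(vessels(co2), function(v) qfrValues(tracePre(v))))

  tiny <- generateCohort(cohortSpec(nVessels = 1, seed = 5))
  expect_equal(nVessels(tiny), 1L)
  expect_s3_class(scoreCohort(tiny), "data.frame")
  expect_error(cohortSpec(nVessels = 0, seed = 1))
})

test_that("multi-vessel patients appear at the configured fraction", {
  spec <- cohortSpec(nVessels = 120, seed = 8, multiVesselFrac = 0.075)
  co <- generateCohort(spec)
  pids <- vapply(vessels(co), patientId, character(1))
  expect_equal(length(unique(pids)), 120L - round(0.075 * 120))
})

test_that("cohort-level gradients and distal values match the emulated cohort", {
  sc <- scoreCohort(generateCohort(cohortSpec(nVessels = 300, seed = 314)))
  expect_gt(mean(sc$delta_qfr), 0.23)
  expect_lt(mean(sc$delta_qfr), 0.28)
  expect_gt(median(sc$distal_qfr), 0.70)
  expect_lt(median(sc$distal_qfr), 0.77)
})
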