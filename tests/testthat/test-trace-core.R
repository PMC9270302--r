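test_that("trace validity rules reject malformed inputs", {
  expect_s4_class(PullbackTrace("V1", c(0, 10), c(1, 0.9)), "PullbackTrace")
  expect_error(PullbackTrace("V1", c(1, 10), c(1, 0.9)), "first position")
  expect_error(PullbackTrace("V1", c(0, 10, 5), c(1, 0.9, 0.8)),
               "strictly increasing")
  expect_error(PullbackTrace("V1", c(0, 10), c(1, 1.2)), "qfr")
  expect_error(PullbackTrace("V1", c(0, 10), c(1, 0.9), "during_pci"), "phase")
})

test_that("resampling interpolates linearly and preserves the vessel length", {
  tr <- PullbackTrace("V1", c(0, 80), c(1.00, 0.75))
  rs <- resampleTrace(tr, 20)
  expect_equal(tracePositions(rs), c(0, 20, 40, 60, 80))
  expect_equal(qfrValues(rs), c(1.00, 0.9375, 0.875, 0.8125, 0.75))

  # already-uniform trace at its own spacing is unchanged
  uni <- linearTrace(60, 1.0, 0.8, step = 0.5)
  expect_equal(resampleTrace(uni, 0.5), uni)

  # non-divisible step keeps the distal landmark as the final point
  odd <- resampleTrace(PullbackTrace("V1", c(0, 13), c(1, 0.9)), 5)
  expect_equal(tracePositions(odd), c(0, 5, 10, 13))

  expect_error(resampleTrace(tr, 0), class = "invalidParameter")
  expect_error(resampleTrace(tr, 81), class = "invalidParameter")
})

test_that("resampling a jittered grid matches per-point interpolation", {
  withr::local_seed(101)
  for (k in 1:25) {
    tr <- jitteredTrace(tvl = runif(1, 40, 80), n = sample(10:60, 1))
    rs <- resampleTrace(tr, 0.5)
    expect_equal(qfrValues(rs),
                 interpOracle(tracePositions(tr), qfrValues(tr),
                              tracePositions(rs)),
                 tolerance = 1e-12)
    # idempotence on the grid
    expect_equal(resampleTrace(rs, 0.5), rs)
  }
})

test_that("monotone envelope is the decreasing isotonic projection", {
  mono <- linearTrace(60, 1.0, 0.75)
  expect_equal(monotoneEnvelope(mono), mono)

  # single upward blip is pooled to the adjacent-violator mean
  tr <- PullbackTrace("V1", c(0, 1, 2, 3, 4),
                      c(0.90, 0.80, 0.82, 0.80, 0.79))
  env <- monotoneEnvelope(tr)
  expect_equal(qfrValues(env), c(0.90, 0.81, 0.81, 0.80, 0.79))
  expect_equal(deltaQFRVessel(env), deltaQFRVessel(tr))

  # output is non-increasing, idempotent, and preserves the mean
  withr::local_seed(7)
  for (k in 1:10) {
    noisy <- compositeTrace(60, 0.99, ramps = rbind(c(10, 50, 0.2)),
                            noiseSd = 0.01)
    env <- monotoneEnvelope(noisy)
    expect_true(all(diff(qfrValues(env)) <= 1e-12))
    expect_equal(monotoneEnvelope(env), env)
    expect_equal(mean(qfrValues(env)), mean(qfrValues(noisy)))
  }
})

test_that("monotone envelope recovers a monotone truth under noise", {
  withr::local_seed(2024)
  sigma <- 0.005
  ok <- 0L
  nrep <- 200L
  for (k in seq_len(nrep)) {
    truth <- compositeTrace(60, 0.99,
                            focal = rbind(c(25, 0.15, 1.5)),
                            ramps = rbind(c(35, 55, 0.08)))
    noisy <- PullbackTrace("T", tracePositions(truth),
                           pmin(1.05, pmax(0.01, qfrValues(truth) +
                                             rnorm(121, 0, sigma))))
    dev <- max(abs(qfrValues(monotoneEnvelope(noisy)) - qfrValues(truth)))
    if (dev < 3 * sigma) ok <- ok + 1L
  }
  expect_gte(ok / nrep, 0.95)
})

test_that("index QFR interpolates and respects the vessel extent", {
  tr <- PullbackTrace("V1", c(0, 40, 80), c(0.98, 1.00 - 0.2, 0.60))
  expect_equal(indexQFR(tr, 0), 0.98)
  expect_equal(indexQFR(tr, 80), 0.60)
  seg <- PullbackTrace("V1", c(0, 10), c(1.00, 0.80))
  expect_equal(indexQFR(seg, 5), 0.90)
  # stored grid values are returned exactly
  withr::local_seed(5)
  tr2 <- jitteredTrace()
  expect_identical(indexQFR(tr2, tracePositions(tr2)), qfrValues(tr2))
  expect_error(indexQFR(tr, -1), class = "outOfRange")
  expect_error(indexQFR(tr, 80.5), class = "outOfRange")
})

test_that("vessel gradient is the ostial-minus-distal difference", {
  flat <- linearTrace(50, 1.0, 1.0)
  expect_equal(deltaQFRVessel(flat), 0)
  tr <- linearTrace(65, 0.98, 0.74)
  expect_equal(deltaQFRVessel(tr), 0.24)
  # invariant under resampling (endpoints preserved)
  expect_equal(deltaQFRVessel(resampleTrace(tr, 0.7)), 0.24)
  # raw noisy non-monotone input is flagged
  up <- PullbackTrace("V1", c(0, 10), c(0.90, 0.95))
  expect_warning(d <- deltaQFRVessel(up), "monotoneEnvelope")
  expect_equal(d, -0.05)
})
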