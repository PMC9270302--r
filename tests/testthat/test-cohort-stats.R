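test_that("ROC handles separation, constructed splits and degenerate labels", {
  # perfectly separated scores: AUC 1, cutoff between the groups
  r <- rocOptimalCutoff(c(0.3, 0.4, 0.6, 0.8), c(TRUE, TRUE, FALSE, FALSE),
                        direction = "low")
  expect_equal(r$auc, 1)
  expect_gt(r$optimalCutoff, 0.4)
  expect_lt(r$optimalCutoff, 0.6)
  expect_equal(r$sensitivityAtOptimum, 1)
  expect_equal(r$specificityAtOptimum, 1)

  # high-direction scoring mirrors the rule
  r2 <- rocOptimalCutoff(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE),
                         direction = "high")
  expect_equal(r2$auc, 1)
  expect_gt(r2$optimalCutoff, 0.2)
  expect_lt(r2$optimalCutoff, 0.8)

  expect_error(rocOptimalCutoff(1:5, rep(TRUE, 5)),
               class = "degenerateLabels")
})

test_that("ROC matches exhaustive enumeration and pair-counting AUC", {
  withr::local_seed(88)
  for (k in 1:30) {
    n <- 50
    y <- runif(n) < 0.4
    if (!any(y) || all(y)) next
    s <- rnorm(n, mean = ifelse(y, 0.45, 0.6), sd = 0.12)
    dir <- if (k %% 2 == 0) "low" else "high"
    got <- rocOptimalCutoff(s, y, direction = dir)
    want <- rocOracle(s, y, direction = dir)
    expect_equal(got$auc, want$auc, tolerance = 1e-12)
    expect_equal(got$optimalCutoff, want$cutoff)
    expect_equal(got$sensitivityAtOptimum, want$sens)
    expect_equal(got$specificityAtOptimum, want$spec)
  }
})

test_that("ROC agrees with an independent implementation and the null is 0.5", {
  withr::local_seed(12)
  y <- runif(200) < 0.5
  s <- rnorm(200, ifelse(y, 0.4, 0.55), 0.1)
  got <- rocOptimalCutoff(s, y, direction = "low")
  ref <- suppressMessages(pROC::roc(response = y, predictor = s,
                                    direction = ">", quiet = TRUE))
  expect_equal(got$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-9)

  # label permutation destroys discrimination
  perm <- rocOptimalCutoff(s, sample(y), direction = "low")
  expect_lt(abs(perm$auc - 0.5), 0.08)
  # scores thresholded against themselves are perfectly discriminated
  self <- rocOptimalCutoff(s, s <= median(s), direction = "low")
  expect_equal(self$auc, 1)
})

test_that("Pearson correlation and its Fisher-z interval behave", {
  x <- 1:20
  expect_equal(pearsonR(x, 2 * x)$r, 1)
  expect_equal(pearsonR(x, -x + 7)$r, -1)
  expect_error(pearsonR(x, rep(1, 20)), class = "undefinedCorrelation")
  expect_error(pearsonR(1:3, 2:4), class = "invalidInput")

  withr::local_seed(25)
  rho <- 0.6; n <- 120
  hits <- 0L
  for (k in 1:50) {
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    ci <- pearsonR(x, y)
    hits <- hits + (ci$ciLow <= rho && rho <= ci$ciHigh)
  }
  expect_gte(hits / 50, 0.86)   # nominal 95% coverage
})

test_that("Cohen's kappa matches hand computation and reference software", {
  expect_equal(cohensKappa(letters[1:5], letters[1:5])$kappa, 1)

  # one rater constant: observed equals chance agreement
  a <- rep("x", 10)
  b <- rep(c("x", "y"), 5)
  expect_equal(cohensKappa(a, b)$kappa, 0)

  # 2x2 table [[20, 5], [10, 15]]: po = 0.7, pe = 0.5, kappa = 0.4
  a <- rep(c("p", "p", "n", "n"), times = c(20, 5, 10, 15))
  b <- rep(c("p", "n", "p", "n"), times = c(20, 5, 10, 15))
  k <- cohensKappa(a, b)
  expect_equal(k$kappa, 0.4, tolerance = 1e-12)
  expect_true(k$ciLow < 0.4 && 0.4 < k$ciHigh)
  expect_equal(k$kappa, e1071::classAgreement(table(a, b))$kappa,
               tolerance = 1e-12)

  # invariant under relabeling of the categories
  relab <- c(p = "zebra", n = "aard")
  expect_equal(cohensKappa(relab[a], relab[b])$kappa, k$kappa)
  expect_error(cohensKappa(a, b[-1]), class = "invalidInput")
})

test_that("group tests run ANOVA and Fisher with Bonferroni adjustment", {
  df <- data.frame(
    g = rep(c("A", "B"), each = 10),
    cont = c(rnorm(10, 0), rnorm(10, 3)),
    cat = rep(rep(c("yes", "no"), each = 5), 2))
  out <- groupTests(df, c("cont", "cat"), "g")
  expect_equal(out$method, c("anova", "fisher_exact"))
  # balanced 2x2 table [[5,5],[5,5]] has no association
  expect_equal(out$p[2], 1)
  expect_equal(out$pBonferroni, pmin(1, out$p * 2))
  expect_error(groupTests(df[df$g == "A", ], "cont", "g"),
               class = "invalidInput")
})

test_that("Monte-Carlo Fisher p approximates full enumeration on a small table", {
  # 2 x 3 table, exact p by the network algorithm vs seeded Monte-Carlo
  df <- data.frame(
    g = rep(c("A", "B", "C"), times = c(12, 12, 12)),
    cat = c(rep(c("e", "o"), c(8, 4)), rep(c("e", "o"), c(4, 8)),
            rep(c("e", "o"), c(6, 6))))
  exact <- fisher.test(table(df$cat, df$g))$p.value
  mc <- withr::with_seed(99, groupTests(df, "cat", "g", mcReplicates = 1e5))
  expect_equal(mc$method, "fisher_monte_carlo")
  expect_lt(abs(mc$p - exact), 0.01)
})

test_that("ANOVA keeps its nominal type-I error under the null", {
  withr::local_seed(505)
  reject <- 0L
  nrep <- 400L
  for (k in seq_len(nrep)) {
    df <- data.frame(v = rnorm(48), g = rep(patternLevels(), each = 12))
    p <- groupTests(df, "v", "g")$p
    reject <- reject + (p < 0.05)
  }
  expect_lt(abs(reject / nrep - 0.05), 0.03)
})

test_that("standardized betas recover exact and null relations", {
  df <- data.frame(x = rnorm(50))
  df$y <- 3 * df$x + 5
  out <- suppressWarnings(standardizedBeta(df, "y", "x"))
  expect_equal(out$beta, 1, tolerance = 1e-9)
  expect_lt(out$ciHigh - out$ciLow, 1e-6)

  withr::local_seed(61)
  small <- 0L
  for (k in 1:40) {
    df <- data.frame(x = rnorm(500), y = rnorm(500))
    small <- small + (abs(standardizedBeta(df, "y", "x")$beta) < 0.1)
  }
  expect_gte(small / 40, 0.95)

  df <- data.frame(x = rnorm(30))
  df$z <- df$x
  df$y <- rnorm(30)
  expect_error(standardizedBeta(df, "y", c("x", "z")), class = "collinearity")
})

test_that("cohort analysis reports the study's statistics coherently", {
  sc <- scoreCohort(generateCohort(cohortSpec(nVessels = 150, seed = 6,
                                              multiVesselFrac = 0.075)))
  res <- analyzeCohort(sc, mcReplicates = 2e4)
  expect_equal(sum(res$patternSummary$n), 150L)
  expect_equal(sum(res$tertileSummary$n), 150L)
  expect_true(all(res$patternSummary$suboptimal_rate >= 0 &
                    res$patternSummary$suboptimal_rate <= 1))
  expect_gt(res$pearsonQvpPostQfr$r, 0.4)
  expect_gt(res$kappaPresets$kappa, 0.6)
  # focal pattern predicts higher post-PCI QFR, diffuse lower
  betas <- res$stdBetaPattern
  expect_gt(betas$beta[betas$term == "is_focal"], 0)
  expect_lt(betas$beta[betas$term == "is_diffuse"], 0)
  expect_gt(res$stdBetaQvp$beta, 0)
  # QVP discriminates the patterns it was built to separate
  expect_gt(res$rocFocal$auc, 0.9)
  expect_gt(res$rocDiffuse$auc, 0.9)
  expect_output(print(res), "Cohort analysis")
})

test_that("an all-optimal cohort skips the outcome ROC with a warning", {
  spec <- cohortSpec(nVessels = 25, seed = 77,
                     patternMix = c(focal = 1, serial_lesions = 0,
                                    diffuse = 0, combination = 0))
  co <- generateCohort(spec, instentEventProb = 0, instentLossPerMm = 0)
  sc <- scoreCohort(co)
  expect_true(all(!sc$suboptimal))
  res <- NULL
  w <- capture_warnings(res <- analyzeCohort(sc, mcReplicates = 1e4))
  expect_true(any(grepl("outcome ROC skipped", w)))
  expect_null(res$rocSuboptimal)
  expect_false(is.null(res$pearsonQvpPostQfr))
  expect_equal(sum(res$patternSummary$n), 25L)
})
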