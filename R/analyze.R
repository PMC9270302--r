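#' @include simulate.R stats.R
NULL

#' Score every vessel of a cohort
#'
#' Runs the quantitative method ([vesselMetrics()]) and the qualitative
#' classifier ([classifyVessel()], under both the strict and the lenient
#' preset) on each pre-PCI trace, and joins the PCI outcome.
#'
#' @param cohort a [PullbackCohort-class], or a list of
#'   [SyntheticVessel-class] objects.
#' @param thresholds a [qvpThresholds()] object.
#' @param config classifier configuration for the primary (strict) reading.
#' @param stepMm resampling step (mm).
#' @return A data.frame, one row per vessel: identifiers, ground-truth
#'   pattern, the quantitative metrics, QVP-predicted pattern and tertile,
#'   classified pattern under both presets, post-PCI QFR and the suboptimal
#'   flag.
#' @export
scoreCohort <- function(cohort, thresholds = qvpThresholds(),
                        config = classifierConfig(), stepMm = 0.5) {
  vlist <- if (is(cohort, "PullbackCohort")) vessels(cohort) else cohort
  lenient <- classifierConfig("lenient")
  rows <- lapply(vlist, function(v) {
    m <- vesselMetrics(tracePre(v), stepMm = stepMm)
    clsStrict <- classifyVessel(tracePre(v), config, stepMm)
    clsLenient <- classifyVessel(tracePre(v), lenient, stepMm)
    data.frame(vessel_id = vesselId(v),
               patient_id = patientId(v),
               true_pattern = truePattern(v),
               pattern = as.character(clsStrict$pattern),
               pattern_lenient = as.character(clsLenient$pattern),
               n_focal_drops = sum(clsStrict$events$kind == "focal"),
               n_diffuse_segments = sum(clsStrict$events$kind == "diffuse"),
               tvl_mm = m$tvlMm,
               distal_qfr = m$distalQfr,
               delta_qfr = m$deltaQfr,
               max20 = m$max20,
               lfd_mm = m$lfdMm,
               qvp_index = m$qvpIndex,
               qvp_predicted_pattern =
                 as.character(qvpPredictedPattern(m$qvpIndex, thresholds)),
               qvp_tertile = as.character(qvpTertile(m$qvpIndex, thresholds)),
               post_qfr = postQFR(v),
               suboptimal = postQFR(v) <= thresholds$suboptimalPostQfr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

patternSummary <- function(scored) {
  pat <- factor(scored$pattern, levels = patternLevels())
  agg <- function(f) as.numeric(tapply(scored$qvp_index, pat, f))
  data.frame(pattern = patternLevels(),
             n = as.integer(table(pat)),
             qvp_mean = agg(mean),
             qvp_sd = agg(sd),
             delta_qfr_mean = as.numeric(tapply(scored$delta_qfr, pat, mean)),
             lfd_mean = as.numeric(tapply(scored$lfd_mm, pat, mean)),
             post_qfr_mean = as.numeric(tapply(scored$post_qfr, pat, mean)),
             suboptimal_n = as.integer(tapply(scored$suboptimal, pat, sum)),
             suboptimal_rate =
               as.numeric(tapply(scored$suboptimal, pat, mean)),
             stringsAsFactors = FALSE)
}

tertileSummary <- function(scored) {
  tert <- factor(scored$qvp_tertile,
                 levels = c("lowest", "intermediate", "highest"))
  data.frame(tertile = levels(tert),
             n = as.integer(table(tert)),
             suboptimal_n = as.integer(tapply(scored$suboptimal, tert, sum)),
             suboptimal_rate =
               as.numeric(tapply(scored$suboptimal, tert, mean)),
             post_qfr_median =
               as.numeric(tapply(scored$post_qfr, tert, stats::median)),
             stringsAsFactors = FALSE)
}

#' Cohort-level statistical analysis
#'
#' Reproduces the study's statistical battery on a scored cohort: per-pattern
#' summaries; suboptimal-PCI rates by pattern and by QVP tertile; Pearson
#' correlation of the QVP index with post-PCI QFR; ROC analyses of the QVP
#' index for predicting a focal pattern (high scores predict), a diffuse
#' pattern (low scores predict) and a suboptimal PCI result (low scores
#' predict), each with the maximum sensitivity + specificity cutoff; Cohen's
#' kappa between the strict and lenient classifier readings; ANOVA / Fisher
#' group tests with Bonferroni adjustment; and standardized betas of post-PCI
#' QFR on pattern indicators and on the QVP index with patient-clustered
#' errors. A cohort in which no (or every) vessel is suboptimal makes the
#' outcome ROC degenerate; that analysis is then skipped with a warning and
#' reported as `NULL`.
#'
#' @param scored per-vessel table from [scoreCohort()].
#' @param thresholds a [qvpThresholds()] object.
#' @param mcReplicates Monte-Carlo replicates for r x c Fisher tests.
#' @param mcSeed seed for the Monte-Carlo Fisher p-values.
#' @return A list of class `cohortAnalysis` with the components above.
#' @export
analyzeCohort <- function(scored, thresholds = qvpThresholds(),
                          mcReplicates = 1e5, mcSeed = 20260923) {
  qvpAssert(nrow(scored) >= 1L, "invalidInput", "scored cohort is empty")
  res <- list(nVessels = nrow(scored),
              nPatients = length(unique(scored$patient_id)),
              thresholds = unclass(thresholds),
              mcSeed = mcSeed)
  res$patternSummary <- patternSummary(scored)
  res$tertileSummary <- tertileSummary(scored)
  res$suboptimalOverall <- list(n = sum(scored$suboptimal),
                                rate = mean(scored$suboptimal))
  res$medianPrePciQfr <- stats::median(scored$distal_qfr)
  res$medianPostPciQfr <- stats::median(scored$post_qfr)

  orSkip <- function(what, expr) {
    tryCatch(expr, qvpullbackError = function(e) {
      warning(what, " skipped: ", conditionMessage(e))
      NULL
    })
  }
  res$pearsonQvpPostQfr <- orSkip("correlation",
    pearsonR(scored$qvp_index, scored$post_qfr))

  res$rocFocal <- orSkip("focal-pattern ROC",
    rocOptimalCutoff(scored$qvp_index, scored$pattern == "focal",
                     direction = "high"))
  res$rocDiffuse <- orSkip("diffuse-pattern ROC",
    rocOptimalCutoff(scored$qvp_index, scored$pattern == "diffuse",
                     direction = "low"))
  res$rocSuboptimal <- orSkip("outcome ROC",
    rocOptimalCutoff(scored$qvp_index, scored$suboptimal, direction = "low"))

  res$kappaPresets <- cohensKappa(scored$pattern, scored$pattern_lenient)

  scored$suboptimal_factor <- factor(scored$suboptimal,
                                     levels = c(FALSE, TRUE),
                                     labels = c("optimal", "suboptimal"))
  res$groupTests <- orSkip("group tests", withSeed(mcSeed,
    groupTests(scored,
               vars = c("qvp_index", "delta_qfr", "lfd_mm",
                        "post_qfr", "suboptimal_factor"),
               group = "pattern",
               mcReplicates = mcReplicates)))

  scored$is_focal <- scored$pattern == "focal"
  scored$is_diffuse <- scored$pattern == "diffuse"
  res$stdBetaPattern <- orSkip("pattern regression",
    standardizedBeta(scored, "post_qfr", c("is_focal", "is_diffuse"),
                     cluster = "patient_id"))
  res$stdBetaQvp <- orSkip("QVP regression",
    standardizedBeta(scored, "post_qfr", "qvp_index",
                     cluster = "patient_id"))
  class(res) <- "cohortAnalysis"
  res
}

#' @export
print.cohortAnalysis <- function(x, ...) {
  cat(sprintf("Cohort analysis: %d vessels, %d patients\n",
              x$nVessels, x$nPatients))
  cat(sprintf("  suboptimal PCI: %d (%.0f%%); median pre/post QFR %.2f / %.2f\n",
              x$suboptimalOverall$n, 100 * x$suboptimalOverall$rate,
              x$medianPrePciQfr, x$medianPostPciQfr))
  s <- x$patternSummary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-15s n=%3d  QVP %.2f+/-%.2f  suboptimal %.0f%%\n",
                s$pattern[i], s$n[i], s$qvp_mean[i], s$qvp_sd[i],
                100 * s$suboptimal_rate[i]))
  if (!is.null(x$pearsonQvpPostQfr))
    cat(sprintf("  Pearson r(QVP, post-PCI QFR) = %.2f [%.2f, %.2f]\n",
                x$pearsonQvpPostQfr$r, x$pearsonQvpPostQfr$ciLow,
                x$pearsonQvpPostQfr$ciHigh))
  if (!is.null(x$rocSuboptimal))
    cat(sprintf("  suboptimal-PCI ROC: AUC %.2f, optimal QVP cutoff %.2f\n",
                x$rocSuboptimal$auc, x$rocSuboptimal$optimalCutoff))
  cat(sprintf("  kappa (strict vs lenient reading) %.2f [%.2f, %.2f]\n",
              x$kappaPresets$kappa, x$kappaPresets$ciLow,
              x$kappaPresets$ciHigh))
  invisible(x)
}
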