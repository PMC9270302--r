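#' @include utils.R
NULL

#' ROC analysis with the maximum sensitivity + specificity cutoff
#'
#' Builds the empirical ROC curve over all midpoints between adjacent distinct
#' scores (plus infinite end thresholds), computes the area under the curve by
#' the trapezoid rule, and reports the cutoff maximizing the sum of
#' sensitivity and specificity (ties broken towards the smaller threshold).
#' With `direction = "low"` low scores predict the event (an event is called
#' when score <= threshold); with `"high"` the rule is score >= threshold.
#'
#' @param scores numeric predictor values.
#' @param outcome logical (or 0/1) event indicator, same length.
#' @param direction `"low"` (default) or `"high"`.
#' @return A list of class `rocResult`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `optimalCutoff`, `sensitivityAtOptimum`,
#'   `specificityAtOptimum`, `direction`.
#' @export
rocOptimalCutoff <- function(scores, outcome, direction = c("low", "high")) {
  direction <- match.arg(direction)
  outcome <- as.logical(outcome)
  qvpAssert(length(scores) == length(outcome) && !anyNA(scores) &&
              !anyNA(outcome), "invalidInput",
            "scores and outcome must be equal-length and free of NA")
  if (!any(outcome) || all(outcome))
    qvpStop("degenerateLabels",
            "ROC needs both classes present (events: %d of %d)",
            sum(outcome), length(outcome))
  u <- sort(unique(scores))
  thr <- c(-Inf, if (length(u) > 1L) (u[-1L] + u[-length(u)]) / 2, Inf)
  if (direction == "low") {
    sens <- vapply(thr, function(t) mean(scores[outcome] <= t), numeric(1L))
    spec <- vapply(thr, function(t) mean(scores[!outcome] > t), numeric(1L))
  } else {
    sens <- vapply(thr, function(t) mean(scores[outcome] >= t), numeric(1L))
    spec <- vapply(thr, function(t) mean(scores[!outcome] < t), numeric(1L))
  }
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1L] + sens[ord][-length(ord)]) / 2)
  j <- sens + spec
  best <- which(j >= max(j) - 1e-12)
  i <- best[which.min(thr[best])]
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc, optimalCutoff = thr[i],
                 sensitivityAtOptimum = sens[i],
                 specificityAtOptimum = spec[i],
                 direction = direction),
            class = "rocResult")
}

#' @export
print.rocResult <- function(x, ...) {
  cat(sprintf("ROC (%s scores predict the event): AUC %.3f\n",
              x$direction, x$auc))
  cat(sprintf("  optimal cutoff %.2f (sensitivity %.2f, specificity %.2f)\n",
              x$optimalCutoff, x$sensitivityAtOptimum,
              x$specificityAtOptimum))
  invisible(x)
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' @param x,y numeric vectors of equal length (n >= 4), both with nonzero
#'   variance.
#' @param confLevel confidence level of the interval.
#' @return A list with `r`, `ciLow`, `ciHigh`, `n`, `p`.
#' @export
pearsonR <- function(x, y, confLevel = 0.95) {
  qvpAssert(length(x) == length(y) && length(x) >= 4L, "invalidInput",
            "x and y must have equal length >= 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    qvpStop("undefinedCorrelation",
            "correlation undefined: an input has zero variance")
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = confLevel)
  list(r = unname(ct$estimate), ciLow = ct$conf.int[1L],
       ciHigh = ct$conf.int[2L], n = length(x), p = ct$p.value)
}

#' Cohen's kappa with a large-sample confidence interval
#'
#' Chance-corrected agreement `(po - pe) / (1 - pe)` between two categorical
#' ratings of the same items, with the Fleiss-Cohen-Everitt large-sample
#' standard error for the confidence interval.
#'
#' @param a,b equal-length categorical ratings (factor or character) over the
#'   same category set.
#' @param confLevel confidence level.
#' @return A list with `kappa`, `se`, `ciLow`, `ciHigh`, `po`, `pe`, `n`.
#' @export
cohensKappa <- function(a, b, confLevel = 0.95) {
  qvpAssert(length(a) == length(b) && length(a) >= 2L, "invalidInput",
            "ratings must have equal length >= 2")
  lev <- sort(unique(c(as.character(a), as.character(b))))
  tab <- table(factor(a, levels = lev), factor(b, levels = lev))
  n <- sum(tab)
  p <- tab / n
  po <- sum(diag(p))
  pe <- sum(rowSums(p) * colSums(p))
  if (1 - pe < 1e-12) {
    warning("both raters are constant; kappa is undefined, returning NA")
    return(list(kappa = NA_real_, se = NA_real_, ciLow = NA_real_,
                ciHigh = NA_real_, po = po, pe = pe, n = n))
  }
  k <- (po - pe) / (1 - pe)
  ri <- rowSums(p); cj <- colSums(p)
  A <- sum(diag(p) * (1 - (ri + cj) * (1 - k))^2)
  W <- outer(cj, ri, "+")^2
  B <- (1 - k)^2 * (sum(p * W) - sum(diag(p) * diag(W)))
  C <- (k - pe * (1 - k))^2
  se <- sqrt(max(0, A + B - C) / (n * (1 - pe)^2))
  z <- stats::qnorm(1 - (1 - confLevel) / 2)
  list(kappa = k, se = se,
       ciLow = max(-1, k - z * se), ciHigh = min(1, k + z * se),
       po = po, pe = pe, n = n)
}

#' Group comparisons across functional patterns
#'
#' Compares each named variable between groups: continuous variables by
#' one-way ANOVA, categorical variables by the Fisher exact test
#' (hypergeometric enumeration for 2x2 tables; seeded Monte-Carlo with
#' `mcReplicates` replicates for larger tables). Bonferroni-adjusted p-values
#' across the tested variables are returned alongside the raw ones.
#'
#' @param data a data.frame.
#' @param vars character vector of column names to test.
#' @param group name of the grouping column (>= 2 non-empty groups).
#' @param mcReplicates Monte-Carlo replicates for r x c Fisher tests.
#' @return A data.frame with `variable`, `method`, `p`, `pBonferroni`.
#' @export
groupTests <- function(data, vars, group, mcReplicates = 1e5) {
  g <- factor(data[[group]])
  g <- droplevels(g)
  qvpAssert(nlevels(g) >= 2L && all(table(g) > 0L), "invalidInput",
            "need at least two non-empty groups")
  rows <- lapply(vars, function(v) {
    x <- data[[v]]
    qvpAssert(!is.null(x), "invalidInput", "no column named '%s'", v)
    if (is.numeric(x)) {
      p <- stats::anova(stats::lm(x ~ g))[1L, "Pr(>F)"]
      data.frame(variable = v, method = "anova", p = p,
                 stringsAsFactors = FALSE)
    } else {
      tab <- table(droplevels(factor(x)), g)
      if (nrow(tab) < 2L) {
        warning("variable '", v, "' is constant; Fisher test skipped")
        return(data.frame(variable = v, method = "degenerate", p = NA_real_,
                          stringsAsFactors = FALSE))
      }
      p <- if (all(dim(tab) == c(2L, 2L)))
        stats::fisher.test(tab)$p.value
      else
        stats::fisher.test(tab, simulate.p.value = TRUE,
                           B = mcReplicates)$p.value
      data.frame(variable = v,
                 method = if (all(dim(tab) == c(2L, 2L))) "fisher_exact"
                          else "fisher_monte_carlo",
                 p = p, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$pBonferroni <- stats::p.adjust(out$p, method = "bonferroni")
  out
}

#' Standardized regression coefficients with cluster-robust errors
#'
#' Z-standardizes the outcome and every predictor, fits a linear model, and
#' reports standardized coefficients with confidence intervals from a
#' cluster-robust (CR0) covariance grouped by `cluster` - an approximation to
#' a patient-level random-intercept model that is near-identical when few
#' patients contribute more than one vessel. Without `cluster` the ordinary
#' covariance is used.
#'
#' @param data a data.frame.
#' @param outcome name of the numeric outcome column.
#' @param predictors character vector of predictor columns (numeric or
#'   logical; logical indicators are standardized like any other predictor).
#' @param cluster optional name of the clustering column (e.g. patient id).
#' @param confLevel confidence level.
#' @return A data.frame with `term`, `beta`, `se`, `ciLow`, `ciHigh`, `p`
#'   (intercept omitted).
#' @export
standardizedBeta <- function(data, outcome, predictors, cluster = NULL,
                             confLevel = 0.95) {
  n <- nrow(data)
  qvpAssert(n > length(predictors) + 2L, "invalidInput",
            "need n > number of predictors + 2")
  zscale <- function(v, name) {
    v <- as.numeric(v)
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0)
      qvpStop("collinearity", "variable '%s' has zero variance", name)
    (v - mean(v)) / s
  }
  df <- data.frame(.y = zscale(data[[outcome]], outcome))
  for (v in predictors) df[[v]] <- zscale(data[[v]], v)
  fit <- stats::lm(.y ~ ., data = df)
  if (anyNA(stats::coef(fit)))
    qvpStop("collinearity", "singular design: predictors are collinear")
  vc <- if (is.null(cluster)) stats::vcov(fit)
  else sandwich::vcovCL(fit, cluster = factor(data[[cluster]]), type = "HC0")
  est <- stats::coef(fit)
  se <- sqrt(diag(vc))
  z <- stats::qnorm(1 - (1 - confLevel) / 2)
  out <- data.frame(term = names(est), beta = unname(est), se = unname(se),
                    ciLow = unname(est - z * se),
                    ciHigh = unname(est + z * se),
                    p = unname(2 * stats::pnorm(-abs(est / se))),
                    stringsAsFactors = FALSE)
  out[out$term != "(Intercept)", , drop = FALSE]
}
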