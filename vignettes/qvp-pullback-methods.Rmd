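---
title: "Functional CAD patterns from QFR virtual pullbacks: models and methods"
author: "qvpullback authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional CAD patterns from QFR virtual pullbacks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qvpullback)
```

## The measurement model

A QFR virtual pullback is a sampled curve $q(x)$ of quantitative flow ratio
against position $x$ (mm from the ostium, 0 at the proximal landmark, the
last sample at the total vessel length TVL). Physiologically $q$ can only
fall from ostium to tip — pressure is lost, never recovered — so upward
excursions in a measured trace are noise. `qvpullback` therefore
pre-processes every trace in two parameter-light steps before any drop
metric is computed:

1. **Uniform resampling** (`resampleTrace()`, default 0.5 mm) by linear
   interpolation. Vendor software does not document its sampling density;
   0.5 mm is our choice, fine enough that a 2-mm lesion shoulder spans
   several samples while keeping a 80-mm vessel at 161 points.
2. **Decreasing isotonic projection** (`monotoneEnvelope()`), the
   least-squares non-increasing fit via pool-adjacent-violators
   (`stats::isoreg` on the negated values). It is order-preserving,
   idempotent, mean-preserving and has no tuning parameter; we deliberately
   apply no other smoothing.

All downstream quantities ("drop", "decline", windowed losses) are defined
on the projected trace, which makes them well defined under noise.

## Quantitative method: the QVP index

For a pre-processed trace the package computes

$$\mathrm{QVP} = \frac{1}{2}\left[\frac{\mathrm{MaxQFR}_{20\,\mathrm{mm}}}
{\Delta \mathrm{QFR}_{\mathrm{vessel}}} +
\left(1 - \frac{\mathrm{LFD}}{\mathrm{TVL}}\right)\right]$$

- $\Delta \mathrm{QFR}_{\mathrm{vessel}}$: ostial minus distal QFR
  (`deltaQFRVessel()`).
- $\mathrm{MaxQFR}_{20\mathrm{mm}}$: the largest loss across any 20-mm
  window lying fully inside the vessel (`maxDropOverWindow()`); ties break
  toward the most proximal start. Windows never extend past the distal
  landmark; a vessel no longer than the window uses the whole-vessel
  gradient (its single "window" is the vessel).
- $\mathrm{LFD}$: total length of declining vessel
  (`functionalDiseaseLength()`). A 0.5-mm grid cell is *diseased* when its
  downward slope exceeds `slopeEps = 0.002` QFR/mm; runs of diseased cells
  closer than `mergeGapMm = 4` mm are fused into one segment.

A perfectly focal vessel concentrates its whole gradient inside one window
(first term 1) over a short segment (second term near 1), giving QVP near
1; a vessel declining uniformly over its whole length gives
$\mathrm{QVP} = 10/\mathrm{TVL}$, near 0. The index is undefined for
disease-free vessels; below a gradient of `minDelta = 0.02` the package
raises a `noFunctionalDisease` error rather than returning a sentinel,
because the ratio term is numerically meaningless there.

Two numeric choices deserve justification because no published criterion
exists for them:

- `slopeEps = 0.002` QFR/mm separates real decline from isotonic staircase
  flats; diffuse disease in the emulated cohort has slopes of 0.0036–0.0041
  QFR/mm, comfortably above it.
- `mergeGapMm = 4` mm: the isotonic projection of a shallow noisy ramp is a
  staircase whose flat treads are commonly 2–3 mm long; a smaller merge gap
  fragments one diseased region into many short pieces (and a longer one
  risks bridging genuinely separate lesions, which our generator keeps at
  least 6 mm of plateau apart). Both parameters are exposed in
  `classifierConfig()` and `vesselMetrics()`.

Published decision cutoffs are collected in `qvpThresholds()` with the
printed boundary semantics kept exactly: QVP > 0.71 predicts focal disease,
≤ 0.51 diffuse disease, ≤ 0.57 a suboptimal PCI result; tertiles are
≤ 0.54 / ≤ 0.71 / > 0.71; the suboptimal endpoint is post-PCI QFR ≤ 0.89.

## Qualitative method: reading drops and declines

`detectDrops()` quantifies the visual reading rules:

- **Focal drop**: a loss ≥ 0.05 within a window ≤ 10 mm *that contains a
  steep core* — at least 0.03 lost over some 4-mm sub-interval (windows
  narrower than 4 mm qualify outright). The core requirement
  operationalizes "clear evidence of a focal drop": a noisy stretch of
  diffuse decline can accumulate 0.05 over 10 mm (its zero-noise bound in
  our cohorts is 0.041), but loses well under 0.03 over any 4 mm, while a
  genuine step with a 1–2 mm shoulder concentrates more than half its
  magnitude there. Without the core predicate roughly 44% of noisy diffuse
  vessels are misread as containing a focal drop; with it, recovery at the
  default noise is essentially perfect.
- Candidate windows are accepted greedily by descending magnitude
  (preferring tighter, then more proximal windows — the human reader takes
  the steepest step-up first), rejecting candidates that overlap an
  accepted event or are not separated from it by ≥ 5 mm of near-plateau
  (< 0.01 lost across the gap). "Separated" has no published number; 5 mm
  is our choice, exposed in `classifierConfig()`.
- **Diffuse decline**: the merged diseased segments, minus the accepted
  focal windows, that remain ≥ 15 mm long and lose ≥ 0.05 cumulatively.
  These bounds are chosen so that diffuse disease of the emulated cohort
  (30–55 mm of declining vessel) is always detected while the tails of a
  focal step (total diseased span ≤ 16 mm, of which ≤ 6 mm survives
  exclusion) never are.

`classifyPattern()` then maps events to the four patterns: one focal event
→ *focal*; two or more → *serial lesions*; diffuse only → *diffuse*; any
mixture → *combination* (a vessel with two focal drops **and** a diffuse
segment is a combination, not serial — the mixture rule covers every
mixture). The pipeline is deterministic: identical traces give identical
events and labels.

The study's two-reviewer workflow cannot be reproduced with human readers;
`scoreCohort()` instead classifies every trace under two presets — *strict*
(the defaults) and *lenient* (slightly smaller and closer drops admitted,
shorter diffuse declines) — and `analyzeCohort()` reports Cohen's kappa
between the two readings. This emulates inter-reader disagreement only in
the sense of threshold sensitivity; it cannot model perceptual disagreement.

## The synthetic cohort

No patient-level data are deposited, so `generateCohort()` builds cohorts
with known ground truth. Defaults emulate the published study conditions:
120 vessels (111 patients when `multiVesselFrac = 0.075`), pattern mixture
43 / 17 / 12 / 28% (focal / serial / diffuse / combination), TVL uniform on
55–80 mm, ostial QFR 0.97–1.0, distal pre-PCI QFR targeted to 0.70–0.77,
and i.i.d. Gaussian trace noise with SD 0.005 QFR units (about the
resolution at which published QFR values are reported).

Lesion components are the simplest shapes satisfying the reading rules:

- **Focal**: a logistic step with transition scale 1–1.6 mm, so the steep
  core fits the 10-mm rule and the detected diseased span (≈ 13–16 mm)
  matches reported focal lesion lengths (14 [9–18] mm).
- **Diffuse**: a linear ramp whose slope is capped at 0.0041 QFR/mm so its
  steepest 10-mm drop (≤ 0.041) stays clearly below the 0.05 focal
  threshold. Jointly with the distal-QFR target this forces diffuse
  archetypes onto vessels ≥ ~66 mm with extents of ~48–62 mm — consistent
  with the reported diffuse group (TVL 67 [62–70] mm, diseased length 45
  [30–55] mm), and a genuine geometric constraint of the rule system, not a
  tuning knob.
- **Serial**: two focal steps splitting the gradient 55–65 / 45–35%, their
  centers 25–35 mm apart so at least ~11 mm of plateau separates the cores.
- **Combination**: one focal step (0.085–0.17) plus one ramp (26–36 mm) at
  least 6 mm of plateau apart, in random order along the vessel.

Zero-noise archetypes satisfy their generating pattern's rules *by
construction*, which gives the generator–classifier closure property its
teeth: the classifier must read back the generating pattern with
probability 1 at zero noise and ≥ 95% under default noise (the test suite
verifies both; measured recovery at SD 0.005 is ≈ 100%).

### PCI simulation

`simulatePCI()` is mechanistic bookkeeping, not a fitted outcome model.
Under the default `stent-focal-components` strategy every focal component
is stented (component extent plus 1 mm margin, ≈ 16 mm per stent) within a
40-mm total budget; a central 12–22 mm of the ramp is additionally stented
in combination vessels, and 26–38 mm in pure diffuse vessels (reported
stented lengths: 19–33 mm medians). Components fully covered by a stent
lose their drop entirely; a partially covered component keeps its drop in
proportion to the uncovered length, with a ramp's residual gradient living
on the uncovered portions. The alternative `stent-max-drop-segment`
strategy places a single stent over the maximal-drop window.

In-stent losses model the residual gradients that make even well-covered
lesions occasionally suboptimal: a uniform loss of up to 0.0015 QFR/mm of
stent, plus — with probability 0.12 *per stent* — one focal in-stent drop
of 0.03–0.13. Total in-stent loss is capped below the drop the stents
removed, so simulated PCI never worsens a vessel. The per-stent risk means
multi-stent strategies (serial, combination) carry proportionally more
risk, reproducing the reported ordering of suboptimal-PCI rates (focal
lowest, diffuse/combination highest) and the decreasing rate across QVP
tertiles. We make no claim of matching the clinical correlation (0.62) or
C-statistic (0.80) numerically — those depend on the unavailable patient
data; on default cohorts the package observes r ≈ 0.66–0.73 and AUC
≈ 0.82–0.86, and only the directions are contractual.

What the generator does **not** emulate: pressure–flow physics, vessel
taper and side-branch step-downs, reader-perception noise, correlated
(non-i.i.d.) measurement error along the trace, untreated-lesion operator
error beyond stent-coverage bookkeeping, or the joint distribution of
lesion geometry with clinical covariates. Passing tests on synthetic
cohorts therefore demonstrates internal consistency of the rule system and
the index, not clinical validity on real pullbacks.

## Cohort statistics

`analyzeCohort()` reproduces the study's statistical battery on a scored
cohort:

- **ROC / optimal cutoffs** (`rocOptimalCutoff()`): empirical ROC over all
  midpoints between adjacent distinct scores (± infinite ends), AUC by the
  trapezoid rule, optimum maximizing sensitivity + specificity with ties
  broken toward the smaller threshold; cutoffs are reported to 2 decimals.
  Direction is explicit (low QVP predicts suboptimal PCI and diffuse
  disease; high QVP predicts focal disease).
- **Pearson correlation** with Fisher-z confidence interval
  (`stats::cor.test`).
- **Cohen's kappa** with the Fleiss–Cohen–Everitt large-sample variance for
  its interval (no installed package provides a kappa CI; the point value
  is cross-checked against `e1071::classAgreement` in the tests). Published
  analyses rarely state their kappa CI method; this one is our choice.
- **Group comparisons** (`groupTests()`): one-way ANOVA for continuous
  variables; Fisher's exact test for categorical ones (exact network
  algorithm for 2×2, seeded Monte-Carlo with 10^5 replicates for larger
  tables, seed recorded in the report); Bonferroni-adjusted p-values
  alongside raw ones.
- **Standardized regression** (`standardizedBeta()`): all variables
  z-scored, ordinary least squares, confidence intervals from a
  cluster-robust (CR0) covariance grouped by patient. This replaces a
  patient-level random-intercept model: with ~8% of patients contributing a
  second vessel the two are near-identical, and the contract we test is
  sign and ordering (focal indicator positive, diffuse negative), not
  coefficient magnitude. The confounder set is configuration, not
  inference: the package adjusts for whatever columns the caller supplies.

Degenerate inputs are handled explicitly rather than silently: a cohort
with no (or only) suboptimal vessels skips the outcome ROC with a warning;
constant variables skip their group test; zero-variance predictors raise a
`collinearity` error.

## Problem sizes and determinism

The test suite and the acceptance script use cohorts of up to 500 vessels
and oracle sweeps of 200 seeded instances — sizes at which every
brute-force oracle (exhaustive window scans, per-cell segmentation,
candidate-window enumeration, threshold enumeration with pair-counting AUC)
runs comfortably on one CPU while leaving the sampling error of stochastic
checks well below the tested margins. Every random draw flows from an
explicit seed (cohort seeds fan out to per-vessel sub-seeds), so identical
configuration and seed give byte-identical pipeline outputs; timestamps
appear only in log messages on stderr, never in data files.

## Known limitations

- The LFD criterion is necessarily a numeric convention; published analyses
  derived it from vendor software whose rule is undocumented.
- The steep-core quantification of "clear" focal evidence, the 5-mm
  separation rule and the diffuse length/drop minima are our numeric
  choices for rules the literature states only visually; all are
  config-exposed.
- QVP has not been compared head-to-head with the motorized-pullback
  pressure-gradient index here; that requires paired invasive data.
- Synthetic cohorts cannot establish the clinical effect sizes; they
  establish that the implementation reads its own archetypes correctly and
  reproduces the direction of every published association.
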