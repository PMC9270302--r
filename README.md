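# qvpullback

Functional pattern analysis of coronary QFR virtual pullback traces.

## The problem

Quantitative flow ratio (QFR) estimates fractional flow reserve along a
coronary vessel from angiography alone. Moving the *index QFR* cursor along
the analysed vessel yields a point-by-point QFR-versus-position curve — the
**virtual pullback** — analogous to a motorized pressure-wire pullback. The
shape of the pre-PCI pullback carries prognostic information: a sharp local
step-up marks a focal stenosis a stent can fix, while a long progressive
decline marks diffuse disease that often leaves a poor functional result
(post-PCI QFR ≤ 0.89) even after technically successful stenting.

`qvpullback` implements both readings of that curve for interventional
cardiology researchers:

- **Qualitative method** — rule-based detection of focal drops (≥ 0.05 lost
  within 10 mm, with a steep core) and diffuse declines (≥ 0.05 lost over
  ≥ 15 mm of continuously declining vessel), classifying each vessel as
  *focal*, *serial lesions*, *diffuse*, or a *combination*.
- **Quantitative method** — the QFR virtual pullback index,

  ```
  QVP_index = [ (MaxQFR_20mm / ΔQFR_vessel) + (1 − LFD / TVL) ] / 2
  ```

  where `MaxQFR_20mm` is the maximal QFR drop over any 20-mm window,
  `ΔQFR_vessel` the ostial-minus-distal QFR difference, `LFD` the length of
  vessel with functional disease, and `TVL` the total vessel length.
  Values near 1 indicate focal disease, values near 0 diffuse disease;
  QVP > 0.71 predicts a focal and QVP ≤ 0.51 a diffuse pattern, and
  QVP ≤ 0.57 predicts a suboptimal PCI result.

Because the clinical dataset behind these definitions is not publicly
deposited, the package ships a first-class synthetic-data module that
generates pullback cohorts with known ground truth (lesion geometry,
pattern mixture, vessel length and distal-QFR distributions matched to the
published cohort) and a mechanistic PCI simulator (stents remove covered
drops; partially covered diffuse gradients persist proportionally), so the
whole analysis chain is testable end to end.

## Worked example

```r
library(qvpullback)

co <- generateCohort(cohortSpec(nVessels = 120, seed = 120,
                                multiVesselFrac = 0.075))
co
#> PullbackCohort: 120 vessels (seed 120)
#>   realized mix: focal 53, serial_lesions 17, diffuse 18, combination 32

sc <- scoreCohort(co)
analyzeCohort(sc, mcReplicates = 2e4)
#> Cohort analysis: 120 vessels, 111 patients
#>   suboptimal PCI: 34 (28%); median pre/post QFR 0.74 / 0.95
#>   focal           n= 53  QVP 0.87+/-0.03  suboptimal 9%
#>   serial_lesions  n= 17  QVP 0.60+/-0.04  suboptimal 12%
#>   diffuse         n= 17  QVP 0.28+/-0.03  suboptimal 82%
#>   combination     n= 33  QVP 0.45+/-0.05  suboptimal 39%
#>   Pearson r(QVP, post-PCI QFR) = 0.68 [0.56, 0.76]
#>   suboptimal-PCI ROC: AUC 0.82, optimal QVP cutoff 0.48
#>   kappa (strict vs lenient reading) 0.83 [0.75, 0.91]
```

The per-vessel quantitative metrics are available directly:

```r
vesselMetrics(tracePre(vessels(co)[[1]]))[ ,
  c("tvlMm", "distalQfr", "deltaQfr", "max20", "lfdMm", "qvpIndex")]
#>    tvlMm distalQfr deltaQfr max20 lfdMm qvpIndex
#> 1 76.529     0.703    0.284 0.279  17.5    0.878
```

A vessel 76.5 mm long loses 0.284 QFR units ostium-to-tip, essentially all
of it (0.279) inside one 20-mm window, with only 17.5 mm of diseased
length — a focal vessel (QVP 0.88, above the 0.71 focal cutoff), and a good
candidate for an optimal PCI result.

Individual traces are plain two-column TSV files (`position_mm`, `qfr`) read
and written by `readTrace()` / `writeTrace()`. A thin command-line wrapper at
`inst/cli/qvp-pullback.R` chains the pipeline stages
(`simulate | score | classify | analyze | full-run`).

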