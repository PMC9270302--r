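Package: qvpullback
Title: Functional Pattern Analysis of Coronary QFR Virtual Pullback Traces
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing quantitative flow ratio (QFR) virtual
    pullback traces of coronary vessels before and after percutaneous
    coronary intervention (PCI). The package classifies the functional
    pattern of coronary artery disease (focal, serial lesions, diffuse,
    combination) from the pre-PCI trace by rule-based drop detection,
    computes the QFR virtual pullback index (QVP index) from the maximal
    QFR drop over 20 mm and the length of vessel with functional disease,
    simulates PCI on synthetic vessels with known ground truth, and runs
    the cohort-level statistics (ROC optimal cutoffs, tertile analysis,
    Pearson correlation, Cohen's kappa, ANOVA/Fisher tests, standardized
    regression with cluster-robust errors).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    e1071,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'stats.R'
    'trace-core.R'
    'qvp.R'
    'classify.R'
    'simulate.R'
    'analyze.R'
    'io.R'
    'pipeline.R'
    'qvpullback-package.R'
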