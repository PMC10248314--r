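Package: eindex
Title: The Erdodi Index Model of Performance Validity Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multivariate aggregation of performance validity tests with the
    Erdodi Index (EI): embedded validity indicators are recoded onto a 0-3
    ordinal failure scale from configurable cutoffs, summed, and
    trichotomized into Pass, Borderline, and Fail. Includes the
    diagnostic-accuracy machinery used to calibrate such indices (base rates
    of failure, sensitivity/specificity/overall-correct-classification
    cutoff sweeps, nonparametric AUC with Hanley-McNeil intervals,
    cross-range likelihood ratios, Cohen's d and phi-squared effect sizes),
    criterion groupings built from free-standing validity tests, a
    synthetic-cohort generator with a latent credibility state for
    end-to-end testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
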