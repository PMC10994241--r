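Package: matchscore
Title: Molecular Matching Score and Outcome Analysis for Precision Oncology Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how completely a drug regimen targets a tumour's
    deleterious molecular alterations and immune biomarkers as a percent
    Matching Score (0-100), using a rules-based drug-target knowledge base
    (synergy pairs, anti-VEGF/TP53 and BRCA/PARP-platinum matching
    conventions, checkpoint-inhibitor biomarker tiers). Includes the
    cohort-level outcome analysis that accompanies the score: Kaplan-Meier
    curves, log-rank and Cox proportional-hazards comparisons, Fisher and
    odds-ratio contingency analysis of clinical benefit, a univariate screen
    feeding multivariate models, and ROC (Youden) cutoff selection for
    dichotomizing the score. A synthetic cohort generator emulating the
    molecular structure of carcinoma-of-unknown-primary (CUP) cohorts makes
    the whole pipeline testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    survival,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
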