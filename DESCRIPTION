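Package: postpipe
Title: Scoring and Validation of Post-Flow-Diverter ("Post-Pipeline") Headache
Version: 0.1.0
Authors@R:
    person("Postpipe", "Maintainers", email = "maintainers@postpipe.example.org",
           role = c("aut", "cre"))
Description: Implements a structured scoring system for secondary headache
    after flow-diverter stenting of unruptured intracranial aneurysms
    ("post-pipeline headache"), together with the full analysis pipeline
    around it: five-way post-procedural outcome classification, expert-panel
    content validity indices (I-CVI, S-CVI/Ave), cut-off validation against
    independent rater labels (single-threshold and binormal ROC), exact and
    nonparametric cohort comparisons (Fisher, Mann-Whitney, Shapiro-Wilk),
    multivariable logistic regression odds-ratio tables, and a synthetic
    cohort generator plus a deterministic fixture cohort reproducing the
    published marginal counts, so every stage is testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
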