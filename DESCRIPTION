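Package: ghdrule
Title: Derivation and Validation of a Clinical Prediction Rule for
    Pediatric Growth Hormone Deficiency
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to derive and validate a high-specificity clinical
    prediction rule for growth hormone deficiency (GHD) in children with
    growth failure. Implements operational predictor definitions from raw
    clinical measurements, era-dependent case ascertainment from growth
    hormone stimulation test peaks, odds-ratio association panels for 2x2
    tables including zero-cell exact-conditional intervals, gain-ratio
    (C4.5-style) decision-tree induction with false-positive branch
    pruning, tree-ensemble feature relevance, the final clinical rule as a
    traceable classifier, diagnostic-performance evaluation (Wilson score
    intervals, likelihood ratios, number needed to test, exact binomial
    significance), and a seeded synthetic-cohort generator calibrated to
    published contingency structure so the full pipeline runs end to end
    without patient data.
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
    optparse
Config/testthat/edition: 3
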