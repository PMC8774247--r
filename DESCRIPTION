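Package: radselect
Title: All-Relevant Radiomic Feature Selection with Permutation-Calibrated
    Selection-Frequency Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for discriminating two subject groups from large
    brain-derived radiomic feature tables. Provides a feature-schema
    vocabulary for cortical (DKT) and white-matter (JHU-ICBM-81) atlas
    features, a synthetic cohort and feature-table generator with planted
    group effects, an ANOVA coarse screen, an all-relevant (Boruta-style)
    feature selector with shadow features and random-forest importances,
    a repeated stratified k-fold cross-validation harness with
    accuracy/kappa/sensitivity/specificity reporting, and a
    permutation-calibrated binomial significance test on per-feature
    selection frequencies with Bonferroni adjustment and a minimum
    selection-frequency floor.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ranger,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
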