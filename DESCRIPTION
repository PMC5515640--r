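Package: qstphenotype
Title: Sensory Phenotype Stratification from Quantitative Sensory Testing Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Allocates patients with peripheral neuropathic pain to the sensory
    phenotypes sensory loss, thermal hyperalgesia and mechanical hyperalgesia
    (or a healthy-like profile) from 13 z-transformed quantitative sensory
    testing (QST) parameters, using a normalized Gaussian-density similarity to
    phenotype centroids with native handling of missing values. Provides
    deterministic (single best phenotype) and probabilistic (all phenotypes
    above a cutoff, with exclusion rules) allocation, a simplified
    two-parameter protocol, ROC analysis of the healthy-profile probability
    with Youden-index cutoff selection, Cohen's kappa agreement statistics,
    phenotype frequency summaries, power-based sample-size and
    screening-population planning for phenotype-stratified trials, and a
    synthetic cohort generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    e1071,
    optparse
Config/testthat/edition: 3
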