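Package: rxharmonize
Title: Harmonization of Free-Text Medication Records into Therapeutic-Class
    Exposure Indicators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A four-phase, audit-logged curation pipeline that converts
    self-reported free-text medication entries into standardized generic
    drug names, maps them onto a four-level AHFS-style pharmacologic-
    therapeutic class hierarchy, and emits a participant-by-visit binary
    exposure matrix. Standardization combines exact lexicon matching,
    fuzzy matching (character n-gram Jaccard or normalized Levenshtein
    similarity), a reusable expert-curated variant dictionary, and frozen
    review queues for ambiguous or borderline entries. Includes a
    synthetic corpus generator with ground-truth labels for end-to-end
    validation, stage-accounting reports, QA sampling, and audit-chain
    verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
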