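Package: pedsafety
Title: Quantitative Pediatric Drug Safety Profiling from Electronic Medical Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Mines statistically significant drug-diagnosis associations from
    encounter-level electronic medical records using hypergeometric enrichment
    with Bonferroni family-wise error control, clusters drugs into clinical
    condition groups via Jaccard distances on their significant diagnosis sets
    with bootstrap-stability selection of the cluster count, maps pediatric
    drug labeling statements onto a 0-5 safety scale and aggregates safety per
    drug cluster, and compares drug-use patterns between two cohorts aligned
    by diagnosis or by drug. Includes a synthetic cohort generator with
    planted block structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    mclust,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
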