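Package: pathconsensus
Title: Cross-Cohort Pathway Consensus for Tumor Versus Normal Expression Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for multi-cohort pathway analysis of paired
    tumor/normal transcriptomic data. Each cohort is reduced to one row per
    pathway-annotated gene (interquartile-range filtering and maximum-variability
    probe collapsing), pathways are scored per cohort by mean gene-level Student's
    t statistics against a sample-label permutation null, gene-level evidence is
    combined across cohorts with Fisher's method, combined significant genes are
    tested for pathway over-representation with a hypergeometric test, and the
    cross-cohort concordant pathway set is intersected with the enrichment set to
    produce a consensus report. Includes a synthetic multi-cohort study generator
    with planted pathway effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
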