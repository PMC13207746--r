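Package: phoscoreg
Title: Site-Centric Phosphosite Co-Regulation Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for meta-analysing curated phosphoproteomic result tables
    across many studies and experimental conditions. Harmonizes site
    identifiers, applies Class I localization filtering and fold-change/p-value
    differential calling, ranks the predominant phosphosites of a target
    protein, quantifies intra-protein co-occurrence of phosphorylation via
    positive/negative co-regulation ratios, screens phosphosites of other
    proteins for significant co-differential regulation with a one-sided
    Fisher's exact test on a condition-level contingency table, and
    cross-references hits against curated kinase-substrate and
    protein-protein-interaction tables. Includes a synthetic-corpus generator
    with planted co-regulation structure so every stage can be validated
    against known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
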