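Package: lrtalk
Title: Ligand-Receptor Catalog Integration and Tumor-Immune Crosstalk Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying tumor-immune cell communication from
    transcriptomic data. Harmonizes ligand-receptor pair tables from multiple
    source resources into a single deduplicated catalog with evidence labels
    and GO-derived functional group classification, and computes set
    intersection statistics across sources. Implements a rank-based
    interaction-strength statistic for gene pairs on bulk expression matrices
    with permutation p-values, and consensus integration of cell-cell
    communication predictions from multiple single-cell algorithms, evaluated
    by a weighted Kolmogorov-Smirnov enrichment score and top-fraction
    occupancy. Includes deterministic synthetic-data generators so the whole
    pipeline can be exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    fgsea,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
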