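Package: sciquorum
Title: Consensus Differential Expression, Overrepresentation and
    Cell-Type Association for Spinal Cord Injury Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-quantification analysis pipeline for two-group RNA-seq
    count data: three negative-binomial exact-test scorers distinguished
    by normalization strategy (upper-quartile, median-of-ratios, and
    FPKM/total-count), at-least-2-of-3 consensus voting with averaged
    fold changes, Venn set algebra across time-points and injury ages,
    gene-category overrepresentation by binomial test with Bonferroni
    correction, cell-type association against a seven-cell-type CNS
    reference via percentage-of-sum profiles with hierarchical
    clustering, candidate-gene expression profile tables, and a
    ground-truth synthetic count simulator that makes every stage
    testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
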