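Package: psitools
Title: Differential Splicing, Splicing-Alteration Burden, and Allele-Ratio
    Analysis for PSI Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tidy tools for percent-spliced-in (PSI) analysis of alternative
    splicing in two-group RNA-seq designs. Computes PSI from inclusion and
    exclusion junction counts, calls differential splicing with two-sample
    t-tests and Benjamini-Hochberg correction, selects non-redundant events,
    and compares splicing event-type distributions with exact tests. Scores
    per-sample splicing-alteration burden with a robust median/IQR outlier
    rule, builds ranked gene lists from expression and splicing results,
    runs preranked gene-set enrichment with a permutation null, and
    quantifies mutant-allele mRNA fractions with quasi-wild-type
    classification. Ships a synthetic-data generator with planted effects so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    fgsea,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
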