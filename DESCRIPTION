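Package: mirdefense
Title: Small RNA Sequencing Analysis of miRNA-Mediated Insect Defense
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for plant small RNA sequencing
    studies of biotic-stress resistance: seven-rule raw read filtering with
    table-style accounting, priority-ordered small RNA annotation with an
    rRNA quality gate, TPM quantification of known miRNAs, conservation
    grading of miRNA families, novel miRNA calling from hairpin secondary
    structure (MFE/MFEI criteria with a Nussinov-style energy fold),
    MA-plot binomial differential expression with q-value correction and
    three-way DE-type classification, plant miRNA target-site penalty
    scoring with a lenient/strict union set, miRNA/mRNA negative-regulation
    conjoint analysis, hypergeometric GO/KEGG enrichment, and stem-loop
    qRT-PCR relative quantification (2^-ddCt). Ships a synthetic-data
    generator that emulates an eight-library two-genotype, two-timepoint
    design with a ground-truth ledger for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    stringr,
    stringi,
    readr,
    rlang,
    ggplot2,
    generics,
    withr,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
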