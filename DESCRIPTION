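Package: xacomp
Title: Chromosome-Wide Dosage-Compensation Analysis from RNA-Seq Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing X-chromosome dosage compensation from gene-level
    RNA-seq read counts. Converts counts to RPKM under total-count, upper-quartile
    or median library-size normalization, sweeps median X:autosome and
    chromosome-3:chromosome-2 expression ratios across minimum-expression
    thresholds with chromosome-stratified bootstrap confidence intervals, compares
    male and female expression by two complementary ratio methods, profiles the X
    chromosome in sliding windows, tests X-linkage of sex-biased genes with
    Fisher's exact test, flags divergent replicates with a permutation test on
    sum-of-squared expression differences, and simulates negative-binomial count
    data with known compensation status so every stage can be validated against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    dplyr,
    generics,
    GenomeInfoDb,
    ggplot2,
    IRanges,
    S4Vectors,
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
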