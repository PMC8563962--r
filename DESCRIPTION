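Package: rockermeth
Title: Differentially Methylated Region Detection by AUC Segmentation with
    a Heterogeneous Hidden Markov Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects differentially methylated regions (DMRs) between a test
    group (e.g. tumors) and a control group (e.g. matched normal tissue) from
    CpG-level methylation beta values. Each site is summarized by the ROC
    area under the curve (AUC) of the two groups; the genome-ordered AUC
    track is segmented with a three-state hidden Markov model whose
    transition probabilities decay with the genomic distance between
    consecutive sites, and segments are tested for intra-segment homogeneity
    with the Wilcoxon-Mann-Whitney test and filtered by false discovery
    rate. Additional modules score individual samples or cells against a DMR
    catalog with robust Z-scores, merge per-dataset DMR sets into a
    harmonized catalog, simulate benchmark datasets with implanted DMRs, and
    evaluate predictions with site-wise and segment-wise precision, recall,
    F1 and specificity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
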