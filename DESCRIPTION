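Package: stratocyte
Title: Stratified Cell-Type Composition and Cross-Population Conservation
    Analysis for Single-Nucleus Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for population-stratified differential-abundance analysis
    of single-nucleus RNA+ATAC data and for deciding which associations are
    conserved across self-identified population groups. Implements
    quasibinomial logistic regression of within-class cell-subcluster
    proportions on Alzheimer's disease phenotypes with
    heteroskedasticity-robust standard errors and permutation calibration;
    random-effects meta-analysis across population groups with REML
    estimation, the Hartung-Knapp-Sidik-Jonkman adjustment, a restart and
    fallback cascade, and I-squared conservation filtering; continuous
    expression-program rules around a pluggable count factorizer (KL-NMF
    default) including factor-number selection, top-gene reporting, and
    median-score phenotype associations; discrete-taxonomy decision rules
    (nucleus QC, pairwise subcluster merging, clustering quality scores,
    marker filters, consensus label transfer); chromatin-accessibility
    normalization over risk loci; pooled-library demultiplexing design
    validation and genotype-concordance identity assignment; and donor
    molecular subgrouping by correlation-distance Ward clustering with
    silhouette-selected cuts and hypergeometric enrichment. A synthetic-data
    module generates every input with known ground truth so the whole
    pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    GenomicRanges,
    ggplot2,
    igraph,
    IRanges,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    metafor,
    sandwich,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
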