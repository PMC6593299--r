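Package: mirisk
Title: Serum MicroRNA Differential Expression and Polygenic Risk Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for serum circulating microRNA case-control
    studies: reading and validating mature-miRNA count matrices, merging
    precursor-level counts, abundance filtering, median-of-ratios size factors
    and normalized fragments per million (FPM), per-miRNA negative-binomial
    generalized linear models with a Wald test adjusted for age,
    Benjamini-Hochberg correction, log2-fold-change-weighted polygenic
    expression risk scores with ROC/AUC evaluation (DeLong confidence
    intervals, Youden-optimal cutoff), and hypergeometric over-representation
    of validated miRNA target genes against GMT gene-set collections. A
    negative-binomial simulator reproduces the statistical structure of a
    small extreme case-control serum miRNA study so the full pipeline can be
    exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC,
    DESeq2
Config/testthat/edition: 3
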