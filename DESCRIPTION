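Package: scaffoldomics
Title: Quantifying Drug Response in 3D Tumour Scaffold Models from
    Confocal Stacks, Single-Cell Counts, and Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for three analyses commonly combined in
    drug-response studies of 3D tumour models: (1) quantification of
    drug-induced changes in 3D cell clustering from two-channel confocal
    z-stacks, via per-slice intensity sums, Tukey inner-fence slice
    cropping, Otsu thresholding, 3D connected-object extraction and
    volume-density clustering metrics; (2) single-cell expression
    statistics, including molecule-count QC, percent mitochondrial RNA,
    median size-factor normalization, Wilcoxon rank-sum differential
    expression with log-fold-change and Bonferroni rules, dot-plot
    statistics and population fractions; and (3) a multi-level
    systems-biology analysis over DEG-seeded interaction networks, with
    degree/betweenness trimming, network merging with replicate
    accounting, MCODE-style dense-region detection, hypergeometric
    over-representation and cross-network term consistency. A synthetic
    data module generates ground-truthed fixtures for all three
    modalities so every stage is testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
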