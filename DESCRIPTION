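Package: myoatlas
Title: Multi-Tissue Muscle Transcriptome Diversity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested re-implementation of a multi-tissue skeletal-muscle
    transcriptome analysis pipeline: FPKM normalization with mitochondrial
    reads excluded from the per-sample depth denominator, expressed-transcript
    calling and core-set Venn summaries, one-way ANOVA differential expression
    with Benjamini-Hochberg q-values, Euclidean/complete-linkage clustering of
    tissue transcriptomes, bootstrap PCA with per-transcript principal-axis
    correlations, Myh-based fiber-type composition, tissue-specificity (tau)
    scoring and gene-set overlays, cross-species ortholog fold-change
    concordance, and novel splice-junction discovery. Includes a synthetic-data
    generator with planted ground truth (negative-binomial counts, a latent
    fast/slow fiber axis, planted differential expression, mitochondrial load,
    novel junctions, and quota-planted cross-species concordance) so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
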