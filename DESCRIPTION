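Package: atlasEnrich
Title: Developmental Expression Atlas Specificity and GWAS Gene-Set Enrichment
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
        role = c("aut", "cre"))
Description: Tools for linking tissue- and developmental-stage-specific gene
        expression to complex-trait GWAS signal. Provides expression-atlas QC
        and normalization for multi-tissue, multi-stage TPM matrices; the tau
        tissue-specificity index; one-vs-rest differential-expression calling
        of tissue-specific (top-5 percent rule) and stage-specific (fold-change
        and FDR thresholds) gene sets; fuzzy c-means clustering of
        developmental trajectories with minimum-centroid-distance model
        selection; Jaccard comparison and stage association of co-expression
        modules; and a permutation-calibrated sum-of-squared-SNP-effects
        marker-set enrichment test with cis-window SNP-to-gene mapping. A
        synthetic-atlas generator with planted tissue-specific, stage-specific,
        trajectory and GWAS-enrichment structure supports end-to-end
        validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    e1071,
    mclust,
    withr
biocViews: Transcriptomics, GeneExpression, Clustering, GenomeWideAssociation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
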