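Package: braindev
Title: Temporal Regulation Analysis of Lifespan Brain Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising stage-wise transcriptional regulation of
    the developing brain from bulk expression data. Implements covariate-adjusted
    stage ANOVA with Benjamini-Hochberg control and fold-change filtering to call
    temporal differentially expressed genes, Tukey HSD post-hoc stage comparison
    and adjacent-stage developmental DEG calling, waterfall/twin-peak regulation
    profiles with permutation tests of cross-region DEG sharing, Fisher's exact
    gene-set and cell-type enrichment, signed weighted co-expression network
    construction (soft thresholding, topological overlap, dynamic tree cut,
    eigengene merging), and dynamic-network-biomarker tipping-point detection.
    A seeded synthetic lifespan-transcriptome generator with planted ground truth
    makes the full pipeline testable without access to post-mortem brain atlases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
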