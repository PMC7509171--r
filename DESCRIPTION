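Package: tscpath
Title: Pathway-Level Transcriptional Similarity for Drug-Response Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the transcriptional similarity coefficient (TSC), a
    cosine similarity between the diagonal-deleted gene-gene Gram matrices of
    two sample populations restricted to a pathway, and builds on it a
    responder/non-responder classifier for neoadjuvant drug response with
    subsampled leave-one-out cross-validation and majority voting. Includes
    pathway and gene biomarker discovery scored by the concordance index with
    permutation significance, Spearman-similarity hierarchical clustering of
    cohorts, readers and writers for expression tables, GMT gene-set files and
    clinical response tables, and a latent-factor synthetic cohort generator
    that emulates a three-arm neoadjuvant trial with known ground truth so
    that every pipeline stage is testable without access to trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    mclust,
    rlang,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
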