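Package: wsnf
Title: Weighted Similarity Network Fusion for Cancer Subtype Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies cancer subtypes from matched gene (mRNA and
    transcription factor) and microRNA expression profiles by weighting
    each feature with a combination of its regulatory importance and its
    expression variation.  Regulatory importance is computed with a
    modified PageRank over a directed miRNA-TF-mRNA interaction network
    in which rank flows from targets back to their regulators; expression
    variation is the median absolute deviation across samples.  The
    per-feature weights enter a weighted Euclidean patient distance, and
    per-view patient similarity kernels are merged by an iterative
    cross-network diffusion (similarity network fusion) before spectral
    clustering.  Includes expression preprocessing (log2 transform,
    k-nearest-neighbour imputation, low-mean and low-variance filters),
    cluster validation via silhouette widths on the fused similarity and
    multi-group log-rank survival tests, and seeded generators for
    synthetic regulatory networks, planted-subtype expression data and
    survival outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Matrix,
    cluster,
    stats,
    survival,
    utils
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
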