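Package: neuronblast
Title: Neuron Morphology Similarity Search and Clustering
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Pairwise comparison of registered neuron morphologies using the
    NBLAST algorithm. Neurons are represented as clouds of points with unit
    tangent vectors (dotprops); matched nearest-neighbour segments are scored
    under an empirically trained two-dimensional log2-odds scoring matrix over
    segment distance and absolute tangent dot product. Includes SWC skeleton
    input/output and arc-length resampling, scoring-matrix training from
    same-type and random neuron pairs, database search with raw, normalized
    and mean scores, Ward hierarchical clustering and affinity-propagation
    exemplar clustering of score matrices, and a seeded synthetic-neuron
    generator for end-to-end benchmarking.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
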