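Package: mirsimpath
Title: Path-Based miRNA Functional Similarity from miRNA-Disease Associations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes functional similarity between human miRNAs from
    curated miRNA-disease associations and a hierarchical disease ontology
    (MeSH-style tree codes). Diseases are encoded as ancestor-distance
    feature vectors and compared by cosine similarity (CSD); the resulting
    disease similarity network is traversed with damped walk (transferring)
    matrices, and miRNA pairs are scored by a normalized path-weight ratio
    (MFSP). Includes a best-match-average comparator, construction and
    topology analysis of the thresholded miRNA functional network,
    family/cluster benchmark protocols with rank-based significance tests,
    genomic-distance clustering, expression-correlation analysis, and
    deterministic synthetic-data generators for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    xml2,
    withr,
    GenomicRanges,
    IRanges,
    rtracklayer,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
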