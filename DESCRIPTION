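Package: TADclust
Title: Unsupervised Clustering of Hi-C Contact Profiles for TAD Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects topologically associating domains (TADs) in
    intra-chromosomal Hi-C contact matrices by clustering per-bin contact
    profiles. Bins along the matrix diagonal are represented by their full
    row and column contact profiles, grouped with k-means, hierarchical or
    Gaussian-mixture (EM) clustering under Euclidean, Pearson or city-block
    distances, and consecutive same-cluster runs are segmented into
    domains, boundaries and gaps. Domain calls are scored by the
    intra-minus-inter mean contact frequency and the best-scoring call is
    selected over a range of cluster numbers estimated from the data.
    Includes iterative re-clustering of large clusters to resolve
    sub-domains, consistency comparison between two domain annotations,
    ChIP-seq peak enrichment profiles at domain boundaries, and a
    block-matrix simulator with planted domains for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    cluster,
    optparse,
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
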