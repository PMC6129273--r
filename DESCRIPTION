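Package: cnescan
Title: Conserved Non-Coding Element Discovery by Seed, Merge and Extend
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies conserved non-coding elements (CNEs) between a
    reference and a query DNA sequence under user-defined length bounds
    and a relative identity threshold, without whole-genome alignment or
    whole-genome indexes. Anchors are maximal exact matches enumerated
    with a k-mer hash, merged into co-linear chains under an edit-distance
    gap cost, and extended in both directions while the identity threshold
    allows, with edit distances computed by Myers' bit-vector algorithm.
    Includes exon/repeat masking from GFF3/BED annotation, gene-centric
    and coordinate-range search modes, a command-line interface, and a
    seeded synthetic-data generator with planted homologous segments for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    optparse,
    methods,
    parallel,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
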