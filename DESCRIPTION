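Package: chromstate
Title: Chromatin-State Analysis of Histone-Acetylation ChIP-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A reusable pipeline for genome-wide analysis of histone
    acetylation ChIP-seq in mouse embryonic stem cells: read extension and
    max-overlap density-track construction, input normalization, a
    simplified local-enrichment peak caller, TSS-anchored and gene-body
    scaled composite profiles, genomic-feature annotation of peaks,
    k-means chromatin-state classification of promoters (active, bivalent,
    inactive) and enhancers (active, poised), cross-mark correlation, and
    the H3K14ac/H3K9ac ratio statistic that identifies primed inactive
    promoters.  A synthetic-data generator with planted chromatin states
    makes every stage testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    IRanges,
    S4Vectors,
    data.table,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
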