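Package: markstate
Title: Gene-Level Chromatin State Analysis from Histone Mark Peak Intervals
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Calls histone-mark "marked genes" (H3K4me3, H3K36me3, H3K27me3)
    from ChIP-seq peak intervals against gene models, classifies bivalent and
    antagonistic mark co-occurrence, and relates chromatin state to expression
    level, tissue specificity (tau), stress responsiveness and paralog
    divergence across the Brassica subgenomes. Includes metagene profile
    aggregation, ChIP-qPCR and sequential ChIP enrichment arithmetic, a
    generic hypergeometric term-enrichment engine, and a synthetic-data
    generator that emulates the joint statistical structure of the inputs so
    the entire pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
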