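Package: prrtools
Title: Discovery of Polymorphic Regulatory Regions from Multi-Cell-Line
    Chromatin Peaks
Version: 0.1.0
Authors@R:
    person("PRR", "Maintainers", email = "prrtools@example.org",
           role = c("aut", "cre"))
Description: Builds per-marker consensus regulatory regions from
    multi-cell-line histone-mark and open-chromatin peak sets using an
    overlap-fraction retention rule, classifies them into enhancer and
    promoter chromatin states (H3K4me1 without or with H3K4me3), intersects
    them with transcription-factor binding regions and SNP catalogs to call
    polymorphic regulatory regions (PRRs), and implements the downstream
    allele-specific statistics: allele-fraction normalisation with Fisher's
    exact test for allele-specific binding, delta-delta-Ct relative
    expression with multiple reference genes, percent-input ChIP-qPCR
    enrichment, and IUPAC degenerate consensus-motif scanning (ARE/ERE) with
    per-allele impact scores. A seeded synthetic-data module generates
    multi-cell-line peak landscapes, SNP catalogs, allele counts and Ct
    tables with known ground truth so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    yaml,
    optparse,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
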