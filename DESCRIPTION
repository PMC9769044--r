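Package: regland
Title: Regulatory Element Landscapes from Methylomes, Histone Peaks and
    Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers a regulatory-element landscape from whole-genome
    bisulfite methylomes and companion assays: segmentation of lowly
    methylated regions (LMRs) as candidate enhancers, two-sample
    differentially methylated region calling, genomic annotation and
    histone-peak overlap statistics, enhancer-gene linking by negative
    methylation-expression correlation across samples, position-weight
    matrix scanning with exact dynamic-programming p-values and known-motif
    enrichment on repeat-masked sequence, transcription-factor regulatory
    network assembly, and SNP-density enrichment in regulatory regions.
    Includes a synthetic multi-sample data generator with planted ground
    truth so the whole pipeline is testable offline, and an orchestrator
    that runs all stages from a single configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
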