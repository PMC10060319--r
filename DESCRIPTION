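Package: isoquantr
Title: Isoform Detection and Quantification at a Single Locus from Long Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and quantifies transcript isoforms from long-read
    sequencing of a single locus or amplicon (minigene splicing assays,
    targeted RT-PCR products, spike-in controls). Consensus exon coordinates
    are called from the frequency distribution of aligned exon start and end
    positions using a three-rule procedure (frequency threshold, close-peak
    merging, assignment windows); reads whose boundaries all fall inside
    consensus windows are grouped into isoforms by their exon chain and
    quantified as relative abundances. Includes reciprocal base-overlap
    matching against a reference annotation with cosine-similarity scoring of
    abundance vectors, a synthetic amplicon read simulator with known truth,
    and readers/writers for BAM, BED6, GFF3 and GTF.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    IRanges,
    S4Vectors,
    GenomicRanges,
    Rsamtools,
    rtracklayer,
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
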