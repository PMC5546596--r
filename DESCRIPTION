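Package: mnaseqc
Title: Quality Control and Nucleosome-Array Detection for MNase-seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quality-control pipeline for micrococcal-nuclease sequencing
    (MNase-seq) data. Converts aligned reads into nucleosome footprints and
    genome-wide occupancy and center profiles, then computes sample-level QC
    scores: sequencing coverage, a rotational score from the 10-bp AA/TT/AT
    dinucleotide periodicity of nucleosomal DNA, and the nucleosomal DNA
    length estimated from paired-end template lengths or a single-end
    start-to-end distance distribution. Builds TSS-anchored and custom-region
    nucleosome profiles, scores promoter nucleosome-free regions and
    downstream nucleosome phasing, detects well-positioned nucleosome arrays
    genome-wide, and measures their enrichment over promoters and
    DNase-hypersensitive sites. Ships simulators for nucleosome-footprint
    reads, periodic-dinucleotide genomes, and phased barrier-site arrays so
    every component is testable on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils,
    zoo
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
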