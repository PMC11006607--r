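Package: locusforge
Title: Design and Interrogation of Evolutionarily Naive DNA Loci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing synthetic DNA loci that lack evolved
    coding and regulatory information, and for quantifying the genomic
    activity such loci acquire in a host genome. Implements sequence
    reversal without complementation, iterative stochastic CpG
    elimination, synthesis segmentation with overlapping junctions, and
    homology-arm insertion design; dinucleotide composition profiles
    with observed/expected CpG statistics and CpG-island detection;
    sliding-window coverage statistics including copy-number estimation,
    RPGC normalization, relative coverage, peak density, geneless-window
    read counting and replicate correlation; CAGE-derived transcription
    start sites, promoter intervals and TSS-anchored metaplots; and
    seeded simulators that generate host genomes, locus variants and
    sequencing-like signal for end-to-end testing.
License: MIT + file LICENSE
Depends: R (>= 4.1)
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
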