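Package: aluhsf
Title: Heat Shock Factor Binding Sites in Alu Repeats
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing heat shock factor (HSF) binding motifs
    harboured within Alu retroelements. Implements construction and
    calibration of a 13-column HSF position weight matrix, two-strand
    log-odds scanning of upstream and genic regions, a Gibbs site sampler
    for de novo motif discovery, strand-aware classification of motif
    occurrences into Alu/non-Alu and sense/antisense categories, per-gene
    density statistics with Welch t-test group comparisons, projection of
    Alu-internal motif positions onto subfamily consensus coordinates via
    local alignment, and proximity analysis between antisense
    transcription signals and Alu-harboured HSF sites. A seeded
    synthetic-data generator produces genomes, gene models, Alu
    insertions with planted motifs, expression classes and antisense
    probe signals so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: MotifDiscovery, SequenceMatching, Transcription, Repeat
RoxygenNote: 7.3.3
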