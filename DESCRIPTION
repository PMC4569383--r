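Package: hotspotkit
Title: Quantifying Meiotic Recombination Hotspot Activity from Sperm Typing,
    Limiting-Dilution PCR and QTL Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for measuring and modelling the activity of meiotic
    recombination hotspots. Includes demultiplexing and classification of
    barcoded single-sperm amplicon molecules into parental and crossover
    classes with background-corrected centimorgan estimates; most-probable-
    number (Poisson limiting-dilution) quantitation of amplifiable crossover
    and parental molecules from serial-dilution PCR well counts; single-QTL
    marker-regression genome scans with permutation-derived significance
    thresholds, LOD support intervals and genotype effect summaries;
    allele-assignment of hotspot peak intervals by set overlap; and a
    dimer-competition model of PRDM9 multimer formation and competitive
    hotspot binding under a limiting protein pool with allele-specific
    dissociation constants. Seeded generators produce synthetic versions of
    every input with ground-truth bookkeeping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
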