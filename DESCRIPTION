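Package: MCMfootprints
Title: MCM Helicase Footprinting, Origin Licensing Metrics and
    Stochastic Replication-Timing Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for chromatin endogenous cleavage (ChEC)
    footprinting of the MCM2-7 replicative helicase and its relationship
    to genome replication timing. Builds fragment-size-resolved coverage
    tracks and origin-centered fragment-length heat matrices from
    paired-end fragment tables, classifies replication origins as
    carrying single or multiple MCM double-hexamer footprints, computes
    chromosome-scale dispersion and AT-content statistics, calls
    replication initiation and termination zones from polymerase-usage
    (fork-direction) tracks, simulates stochastic whole-genome
    replication driven by MCM density, and performs allele-specific
    (hybrid-genome) replication analysis including the chromosome
    fluctuation statistic. A fully seeded synthetic-data generator
    produces genomes, ChEC fragment libraries, fork-direction tracks,
    S/G1 depth tracks and hybrid SNP reads with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
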