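Package: synthchip
Title: Desk-Scale Simulator for a DRAM-Addressed Electrochemical DNA Synthesis Chip
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the three subsystems of a high-throughput electrochemical
    DNA-synthesis platform: a DRAM-like row/column decoder fabric that addresses
    ten million capacitor-backed microelectrodes through 145 external pins, the
    single-pole RC charge/discharge/refresh dynamics of the per-site storage
    capacitor, and a two-dimensional incompressible two-phase flow solver for the
    static-droplet-array microfluidics that confines deprotection protons to
    per-site droplets.  A synthesis orchestrator turns per-site target
    oligonucleotides into per-cycle, per-base activation masks and drives the
    addressing and dynamics models; seeded fixture generators and plain-text
    readers/writers make every simulation reproducible.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    data.table,
    jsonlite,
    yaml,
    Rcpp,
    Biostrings,
    EBImage,
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
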