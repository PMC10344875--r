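Package: plaeq
Title: Signal Equalization and Quantification for Proximity Ligation Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for designing and analysing dynamic-range-equalized
    solid-phase proximity ligation assays (spPLA). Provides a forward
    equilibrium/binomial model of reporter-DNA generation (Langmuir detection
    antibody binding, binomial 5'/3' label pairing, epitope depletion, bead
    capture saturation and hook effect), a model-based tuning engine that
    equalizes a multiplexed panel of analytes spanning many orders of
    magnitude onto a common reporter output, a sequencing readout pipeline
    (quality filtering, duplicate collapse, exact-similarity barcode
    assignment, UMI counting and control normalization), qPCR trace
    processing (Ct extraction, DNA calibration lines, amplification-cycle
    selection), four-parameter logistic calibration with log-residual
    fitting and guarded inversion, and a fully seeded synthetic-data
    generator (reporter references, FASTQ reads with per-base errors, qPCR
    traces, standards) so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    methods,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
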