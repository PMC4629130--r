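Package: sensillaR
Title: Quantification of Insect Single-Sensillum Recordings and Odorant-Space Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying extracellular single-sensillum recordings
    (SSR) from insect olfactory sensilla and the downstream odorant-coding
    analyses used in chemical ecology: spike detection from voltage traces,
    baseline-subtracted firing rates, peristimulus time histograms,
    tuning-curve kurtosis, response-band and chemical-class summaries,
    odorant-space Euclidean distances with between-group (UPGMA) clustering
    and correlation-matrix PCA, phasic/tonic temporal classification, and
    Hill-equation EC50 fitting of odorant-receptor dose-response data.
    Includes a seeded synthetic-data generator (inhomogeneous-Poisson spike
    trains with refractory dead time, voltage traces, odorant-by-sensillum
    response matrices, and desensitizing voltage-clamp current traces)
    emulating recordings from the six antennal sensillum types of the bed
    bug Cimex lectularius, so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    minpack.lm,
    ape,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse
Config/testthat/edition: 3
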