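Package: cfpsflow
Title: Design, Characterization and Forward Prediction of Cell-Free Gene
    Circuits in Microfluidic Chemostats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolbox for model-based characterization of cell-free
    transcription-translation (TX-TL) gene circuits run in microfluidic
    chemostats under discrete medium-refresh cycles.  Builds coarse-grained
    ODE models of arbitrary circuits assembled from a library of genetic
    building blocks (sigma-factor promoters, repressor operators, RiboJ
    insulators, reporter ORFs), simulates them under time-varying DNA
    inflow protocols, quantifies practical parameter identifiability with
    collinearity indices, searches for information-maximizing inflow
    patterns (Fisher-information optimal experimental design), and fits
    shared kinetic parameters to a database of experiments with a
    population-based least-squares routine that returns parameter
    ensembles rather than point estimates.  Ships reference parameter
    databases and the pulse-decoder and bistable-switch prediction
    circuits, plus a synthetic-data generator for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
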