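Package: atmapr
Title: Activation-Time Mapping of Complex Cardiac Optical-Mapping Recordings
Version: 0.1.0
Authors@R:
    person("atmapr", "developers", email = "atmapr@example.org", role = c("aut", "cre"))
Description: Tools for analysing high-frequency and arrhythmic cardiac
    optical-mapping image stacks. Implements pixel-independent action-potential
    upstroke windowing via Hilbert-transform phase with recursive segmentation,
    automated derivative thresholding (false-discovery-rate controlled),
    activation-time detection including biphasic upstrokes, spatio-temporal
    connected-components wave-front labeling with an automatically estimated
    conduction-block parameter, per-front repolarization and action-potential
    duration mapping, repetitiveness and activation-source classification,
    dynamic activation-map stacks, and a seeded two-variable excitable-media
    simulator with an optical observation model for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    igraph,
    data.table,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
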