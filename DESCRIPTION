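Package: lungpdd
Title: Percentage Depth Dose in Lung-Heterogeneous Slab Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying megavoltage photon percentage depth dose (PDD)
    in soft-tissue/lung slab phantoms. Provides a thermoluminescent dosimeter
    (TLD) reading-to-dose processing chain (batch characterization, session
    stability control, linear calibration, uncertainty propagation),
    Bragg-Gray dose-to-medium conversion from embedded mass collision
    stopping-power tables, a compiled Monte Carlo photon/electron dose engine
    in cylindrical slab geometry with a detector-perturbation workflow,
    analytic heterogeneity-correction algorithms (generalized Batho, modified
    Batho, equivalent tissue-air ratio), PDD comparison and interface-dose
    metrics, and synthetic-data generators for fully reproducible end-to-end
    studies of lateral electronic disequilibrium in small fields.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
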