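Package: palatesup
Title: Palatal-Vault Superimposition of Maxillary Digital Models and Its
    Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Region-restricted rigid superimposition of three-dimensional
    maxillary dental surface meshes and validation of the palatal-vault
    superimposition method against a reference (CBCT-derived) alignment.
    Provides STL input/output with landmark and region-mask sidecars,
    landmark-seeded trimmed point-to-surface iterative closest point
    registration, an occlusal-plane-based anatomical coordinate frame,
    first-molar and central-incisor position and tip/torque measurement with
    crown-patch landmark transfer, signed-deviation statistics (one-sample
    t-tests, intraclass correlation coefficients), and a synthetic palate
    phantom generator with analytic ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
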