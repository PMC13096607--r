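Package: cartifls
Title: Interstitial Fluid Load Support and Friction in Articular Cartilage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Combined computational framework for cartilage tribology under
    creep: an axisymmetric fibril-reinforced poroviscoelastic finite-element
    model of unconfined creep (tension-only viscoelastic collagen network,
    Neo-Hookean nonfibrillar matrix, Darcy flow with strain-dependent
    permeability), creep-curve parameter identification by RMSE minimisation,
    extraction of interstitial fluid load support (IFLS), tribo-rheometer
    signal processing (coefficient of friction, Hersey number, lift-off
    exclusion), strain-IFLS and friction-IFLS regression, Stribeck surfaces,
    nonparametric group statistics, and a synthetic-experiment generator
    emulating healthy and enzymatically degraded osteochondral plug pairs
    lubricated with synovial fluid or saline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    lhs,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
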