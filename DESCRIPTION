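Package: coagflow
Title: Flow-Coupled Spatial Modelling of Tissue-Factor-Initiated Coagulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mechanism-driven simulation of fibrin thrombus formation in a
    two-dimensional perfused channel. A declarative kinetic scheme of the
    tissue-factor (extrinsic) coagulation cascade is coupled to
    advection-diffusion transport in pressure-driven Stokes flow, with a
    fibrin-gelation permeability switch that lets the growing clot obstruct
    the flow that shaped it. Includes the modular-decomposition machinery
    (per-species convection toggles, reaction knockouts, factor additions)
    and the quantitative analysis layer (clotting lagtime, exponential
    lagtime-versus-shear fits, comparative flow-influence and
    flow-sensitivity coefficients, integral extrinsic-tenase kinetics)
    needed to dissect how wall shear rate gates coagulation onset.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    deSolve,
    minpack.lm,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
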