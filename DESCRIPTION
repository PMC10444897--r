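Package: fibrolyse
Title: Flow-Driven Fibrinolysis: Analytic Front Model and
    Lattice-Boltzmann Porous-Clot Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Models the flow-driven breakdown (lysis) of occlusive fibrin
    clots.  Provides an analytical one-dimensional front-propagation model
    in which a pro-fibrinolytic agent accumulates at the clot face and
    degrades fibrin by a second-order reaction, together with calibration
    of the reaction rate against measured front-position time series; and
    a mesoscopic lattice-Boltzmann (BGK) simulator in which the clot is a
    partial-bounce-back porous medium whose local permeability follows
    Davies' law for fibrous media and evolves as a transported anti-fibrin
    agent dissolves the fibers.  Includes synthetic homogeneous and
    heterogeneous clot generators, recanalization observables, seeded
    ensemble experiments, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
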