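Package: macpol
Title: Boolean and Dynamic Modeling of Macrophage Polarization
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-tier characterization of M1 (LPS-driven) and M2 (IL-4/IL-13
    driven) macrophage activation. Provides a generic engine for logical
    interaction hypergraphs with timescale constants, including logical
    steady states under three-valued (Kleene) logic and signed-path
    dependency-matrix classification; ships a refined Boolean model of
    macrophage polarization with scenario runners for knockouts and
    co-regulatory signals; ingests and ternarizes qPCR fold-change panels
    and scores their concordance with Boolean predictions; and couples the
    network tier to a linear ODE model of mRNA expression driven by
    step-function transcription-factor activity, with weighted least-squares
    calibration, profile-likelihood identifiability and transcription-factor
    activity window prediction. A synthetic-data generator emulating the
    Fluidigm-style time-course design makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    yaml,
    igraph,
    deSolve,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    readxl
Config/testthat/edition: 3
biocViews: SystemsBiology, Network, GeneExpression, TimeCourse
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'logic-model.R'
    'dependency.R'
    'expression.R'
    'lss.R'
    'macrophage.R'
    'ode.R'
    'fitting.R'
    'io-export.R'
    'macpol-package.R'
    'synthetic.R'
    'pipeline.R'
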