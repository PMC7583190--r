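Package: synergypd
Title: Multi-Scale Pharmacodynamic Modeling of Cytotoxic Drug Synergy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for quantifying pharmacodynamic interactions between
    cytotoxic drug pairs in cultured cancer cells across three scales of
    observation. Implements a cell-growth kinetic model with Hill-type
    concentration-dependent killing, transit-compartment signal delays and
    an empirical interaction term on the half-maximal kill concentrations;
    an indirect-response ordinary differential equation network for the
    fold-change dynamics of ten apoptosis- and mitosis-related proteins; a
    linked cell-cycle/apoptosis compartment model with Gompertz density
    inhibition, mitotic arrest, mitotic slippage to polyploidy and
    protein-modulated apoptosis; maximum-likelihood estimation with
    heteroscedastic variance models, AIC-based transit-depth selection and
    sequential (fix-upstream, fit-downstream) fitting; and preprocessing
    plus temporal k-means clustering of label-free proteomic expression
    matrices. A synthetic-data module generates every input the pipeline
    consumes so all stages can be exercised and validated without access
    to the original measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    limma,
    stats,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
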