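Package: clustersync
Title: Cluster Synchronization Analysis for Multi-Layer Neuron Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect and analyze exactly synchronized clusters in
    multi-layer networks of heterogeneous neurons with weighted, directed and
    possibly delayed coupling. Finds the coarsest equitable partition of a
    multi-layer network, builds the corresponding quotient dynamical system,
    integrates it (delay differential equations via a fixed-step method-of-steps
    integrator), transforms perturbations to irreducible-representation
    coordinates exposing the transverse block structure, and estimates per-block
    maximum Lyapunov exponents to issue per-cluster stability verdicts.
    Includes conductance-based and Hindmarsh-Rose neuron models, chemical
    (instantaneous and dynamical) and electrical synapse models, and end-to-end
    pipelines for a mollusc swim central pattern generator and a cortical
    connectivity network.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
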