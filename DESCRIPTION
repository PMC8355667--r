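Package: hypersis
Title: Stochastic SIS Epidemics on Hypergraphs with Spectral Extinction Thresholds
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for susceptible-infected-susceptible (SIS) contagion on
    hypergraphs, where the infection rate of a node depends through a
    nonlinear response function on the number of infectious co-members of
    each hyperedge, optionally with a distinct response per hyperedge
    category. Provides the exact individual-level continuous-time Markov
    process (event-driven and discrete-time simulators), the deterministic
    mean-field ODE approximation with analytic Jacobians, and the full
    suite of spectral diagnostics: co-membership matrices, critical
    infection strength, extinction-probability and expected-extinction-time
    bounds, isoperimetric (Cheeger-like) boundary-pressure quantities and a
    non-extinction certificate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
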