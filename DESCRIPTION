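Package: emtnfatc
Title: Multistability Analysis of the NFATc-Coupled EMT Regulatory Circuit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic and ensemble analysis of the coupled
    miR-200/ZEB/SNAIL/E-cadherin/NFATc gene regulatory circuit driving
    epithelial-mesenchymal transition (EMT). Provides shifted-Hill and
    microRNA binding-site ODE models, SNAIL-driven bifurcation and phase
    diagrams with hybrid-window and sensitivity analysis, quasi-steady-state
    reduction with Euler-Maruyama stochastic simulation (mean residence
    times, quasi-potential landscapes, barrier heights), random-circuit
    perturbation ensemble statistics with z-score phenotype calls, and
    degree-preserving sign randomization of the network topology.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
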