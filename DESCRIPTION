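Package: transportmc
Title: Model-Space Exploration for Membrane Transporter Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for exploring the space of thermodynamically consistent
    kinetic models of alternating-access membrane transporters. Generates
    combinatorial state spaces from conformational and binding substates,
    assigns Arrhenius-like rate constants from free-energy parameterizations
    with chemical-potential driving, solves the steady-state chemical master
    equation for probabilities, net flows and species fluxes, and samples
    model space by Metropolis Monte Carlo with tempering against functional
    fitness goals (symport, antiport, substrate-versus-decoy discrimination).
    Includes analysis utilities for chemical-potential sweeps, stoichiometry
    and selectivity, targeted barrier perturbations (ion-leak removal),
    kinetic pathway diagrams, and complete-linkage clustering of flux
    mechanisms across model sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
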