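Package: acidflux
Title: Dynamic Flux Balance Analysis of Fungal Organic Acid Fermentation
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates batch organic-acid fermentation by Aspergillus niger
    with dynamic flux balance analysis (dFBA). Each Euler time-step solves a
    double optimisation: growth is maximised first, then - at fixed growth -
    either phosphate storage (while external phosphate uptake capacity
    exceeds demand) or proton production (once growth is phosphate-limited).
    Substrate uptake is constrained by Michaelis-Menten kinetics with citrate
    inhibition of glucose transport, extracellular glucose oxidase flux is
    forced as a function of pH, and external pH evolves from polyprotic
    acid-dissociation chemistry. Includes a bundled hand-checkable toy
    stoichiometric network, SBML import/export, gene-knockout simulation
    (oah, gox), a bounded-variable simplex solver with an exhaustive
    vertex-enumeration oracle, and a least-squares fitting harness with AIC
    model selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    xml2
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
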