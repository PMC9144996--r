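Package: stmkin
Title: Structural Thermokinetic Modelling of Metabolic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds thermodynamically consistent kinetic metabolic models
    around a reference state. Reaction elasticities are computed from
    thermodynamic forces and enzyme saturation values for modular rate laws
    (mass-action, simultaneous-binding and common modular kinetics), kinetic
    constants satisfying Haldane relationships are reconstructed, and
    Metabolic Control Theory quantities are derived: Jacobians, control and
    response matrices, second-order (synergy) coefficients, linearised time
    courses and spectral noise propagation, including chemical Langevin noise
    from one-way fluxes. Supports sampled model ensembles with stability
    screening, flux projection, max-min driving-force concentration finding,
    FBA- and MoMA-style knockdown synergies, and SBML/SBtab/TSV input and
    output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    deSolve,
    jsonlite,
    yaml,
    xml2,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
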