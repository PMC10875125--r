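Package: camito
Title: Thermodynamic Efficiency of Calcium-Regulated Mitochondrial Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Kinetic model of the cross-talk between cytosolic calcium
    signaling (IP3 receptor release, SERCA uptake, mitochondrial uniporter
    and Na+/Ca2+ exchanger) and mitochondrial energy metabolism (TCA cycle,
    electron transport chain, F1F0-ATPase, adenine nucleotide translocator),
    together with a nonequilibrium chemical-reaction-network thermodynamic
    analysis: per-reaction transformed Gibbs energies, entropy production,
    conservation laws and emergent cycles computed in exact arithmetic,
    nonconservative/driving work decomposition, and the thermodynamic
    efficiency of mitochondrial ATP production in steady-state and
    oscillatory regimes. Includes stiff ODE integration, limit-cycle
    detection and period measurement, bifurcation scans over stimulation
    and substrate levels, and seeded parameter-perturbation scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
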