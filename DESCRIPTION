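Package: stochpn
Title: Stochastic Simulation of Place/Transition Petri Nets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discrete place/transition Petri nets with constant places for
    modelling biochemical reaction systems, and four simulation engines:
    asynchronous and synchronous token-game modes, a constant-rate stochastic
    mode with exponential waiting times, and the Gillespie stochastic
    simulation algorithm (direct method with a dependency graph) together
    with an approximate tau-leaping variant that treats reactions with few
    reactants exactly.  Includes conversion between concentrations and
    molecule counts and between mass-action and stochastic rate constants,
    a mathematical and conditional expression engine for time- and
    state-dependent rates and boundary conditions, seeded replicate
    execution, PNML and XML setup persistence, tab-separated trajectory
    export, and a packaged insulin-receptor recycling model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
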