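Package: enzopt
Title: Enzyme Manipulation Design for Kinetic Metabolic Models by Fuzzy
    Multi-Objective Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for choosing which enzymes of a kinetic (generalized mass
    action or Michaelis-Menten type) metabolic model to over-express or
    repress in order to maximize the synthesis rates of target metabolites.
    Implements the crisp mixed-integer nonlinear formulation with an
    epsilon-constraint on the number of manipulated enzymes and a weighted
    infinite-norm scalarization, and a generalized fuzzy multi-objective
    extension in which metabolite and enzyme resilience goals (the tendency
    of a mutant to settle close to the wild-type steady state) and soft cell
    viability limits enter a delta-augmented min-max goal-attainment
    objective. Includes steady-state solving for power-law and general rate
    laws, exhaustive pattern enumeration with multistart local solves, a
    greedy incremental heuristic for large enzyme sets, a synthetic pathway
    generator, and bundled fixtures for the yeast anaerobic fermentation
    network and a synthetic Escherichia coli central-carbon network.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
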