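Package: netctrl
Title: Exact Controllability Optimization of Directed Weighted Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies minimum sets of external control nodes that render a
    directed weighted network fully controllable under the
    Popov-Belevitch-Hautus (PBH) rank condition.  The selection problem is
    posed as a penalised binary optimisation and solved with a
    quantum-inspired genetic algorithm (qubit chromosomes, adaptive crossover,
    adaptive Q-gate rotation, population catastrophe).  Includes
    maximum-matching and maximum-multiplicity baselines, an exhaustive oracle
    for small networks, generators for Erdos-Renyi, static-model scale-free,
    Newman-Watts small-world, random-regular and complete ensembles with
    candidate-control attachment, topology statistics (degree heterogeneity,
    clustering), and scripted benchmark/sweep experiments.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    parallel,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
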