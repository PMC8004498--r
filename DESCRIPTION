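Package: migrec
Title: Migration-Recombination Dynamics and Their Genealogical Solution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the discrete-time migration-recombination equation, a
    deterministic nonlinear dynamical system for the genetic type distribution
    of a subdivided population evolving under migration between demes and
    recombination among sequence sites. The nonlinear forward iteration is
    solved exactly by Haldane linearisation: the dynamics is embedded into the
    linear evolution of a vector of recombinators indexed by deme-labelled
    partitions of the site set, driven by powers of the transition matrix of
    the labelled partitioning process, a Markov chain tracing the genealogy of
    a single sequence backward in time. Includes combinatorics of the
    (labelled) partition lattice, Monte-Carlo solution via Markov duality,
    limiting and quasi-limiting analysis of the partitioning process, the
    continuous-time analogue with matrix-exponential and ODE solvers, model
    configuration I/O, and a seeded random-model generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
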