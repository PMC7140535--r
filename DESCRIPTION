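Package: mssim
Title: Agent-Based Simulation of Immune Dynamics in Relapsing-Remitting
    Multiple Sclerosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A stochastic, discrete-time, bit-string polyclonal lattice
    agent-based simulator of immune system dynamics extended with
    relapsing-remitting multiple sclerosis pathobiology.  Immune cells carry
    binary-string receptors in a 2^l shape space with Hamming-distance
    complementarity; cells live on 2D hexagonal lattices representing a lymph
    node and a slice of white matter, move by chemotaxis, and interact through
    Bernoulli rules.  Homeostasis follows an Ornstein-Uhlenbeck mean-reverting
    process and T cells undergo two-phase thymic selection.  The disease layer
    models oligodendrocyte injury, myelin basic protein release, tolerance
    breakdown, risk factors (EBV mimicry, HLA predisposition, vitamin D,
    smoking) and five disease-modifying drugs, including a 29-species
    enzymatic-reaction sub-model of DHODH inhibition by teriflunomide.
    Patients are parameterized from clinical features (onset age, oligoclonal
    bands, lesion load) and virtual cohorts can be generated across severity
    strata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    deSolve
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
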