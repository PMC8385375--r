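Package: ddadapt
Title: Population Dynamics of Repair and Checkpoint Adaptation after DNA Damage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stochastic and continuous compartment models of a yeast cell
    population responding to DNA damage, in which checkpoint-arrested cells
    either repair, die, or adapt to the damage (override the DNA damage
    checkpoint) and divide at the risk of dying. Implements the discrete-time
    Markov population model with carrying-capacity division, its three- and
    four-compartment ODE counterparts with logistic growth, saturation-time
    detection, fluctuating damage environments with a random stop time, and
    parameter-sweep experiments: optimal adaptation timing, adaptation
    heterogeneity as a bet-hedging strategy, and the adapted-ancestry
    structure of the surviving population.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
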