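Package: entrosim
Title: Entropy-Distance Agent Simulation of Insistence on Sameness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Agent-based simulator of an entropic account of insistence on
    sameness. An agent with a sequence-graph memory classifies noisy vector
    stimuli by nearest neighbour, tracks surprise and uncertainty as the two
    conditional-entropy components of the entropy distance (variation of
    information) between environment and memory, triggers sensory-overload and
    anxiety events against stochastic thresholds, and reduces the distance
    either by learning or by constraining its environment to the already
    known. Ships synthetic branching sequence environments with
    guideline-inspired transforms (amulets, branch-to-start, option limiting),
    sensory-deprivation regimes with self-stimulation, a digital-twin
    comparison harness, and a therapy planner that greedily maximizes mutual
    information I(R;M) subject to predicted surprise and uncertainty staying
    below interval-censored threshold estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml,
    igraph,
    survival
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
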