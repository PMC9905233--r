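Package: cohesim
Title: Group Cohesion and Exploration in Collective Decision Making Under
    Uncertainty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how group cohesion incentives shape
    exploration and decision quality in groups choosing repeatedly among
    uncertain reward options. Provides a multi-agent epsilon-greedy bandit
    simulator with additive and multiplicative cohesion-bonus schemes,
    behavioral scoring of choice logs (choice score, half-change round)
    and of movement trajectories on hexagonal boards (leadership-
    followership scores, field distribution, weighted clustering),
    generators for synthetic card-choice and movement sessions with known
    ground truth, and mixed-model and mediation analyses of the resulting
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
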