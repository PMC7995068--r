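Package: edgame
Title: Scoring-Based Serious-Game Simulator and Learning Analytics for
    Emergency-Department Logistics
Version: 0.1.0
Authors@R:
    person("edgame", "developers", email = "edgame@example.org", role = c("aut", "cre"))
Description: A headless, seedable round-based simulator of a serious game for
    pediatric emergency-department logistics, together with its complete
    telemetry-analytics chain.  The package generates synthetic patient-profile
    decks and arrival schedules, runs bot-driven game sessions that emit
    JSON-Lines telemetry, scores sessions with a token mechanic built on four
    logistical indicators (production throughput, activity execution, resource
    management, production resilience), codes telemetry into participatory
    behavior sequences, runs lag sequential analysis with adjusted-residual
    z-scores and significance-thresholded transition graphs, regresses
    logistical performance on learning-engagement attributes with a parameter
    recovery harness, and scores Game Experience Questionnaire style Likert
    responses into dimension means.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
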