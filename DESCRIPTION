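Package: jitaisim
Title: Simulation and Tailoring Analysis for Workplace Stress
    Just-in-Time Adaptive Interventions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying just-in-time adaptive intervention (JITAI)
    systems for workplace stress reduction. Provides a discrete-event
    simulator of a sensing-driven deployment (participants, workplace
    telemetry, ecological momentary assessments, nudges and the user
    engagement flow), a deterministic nudge-gating engine built on a
    five-component composite stress score with individualized week-one
    baselines, a feature builder that reconstructs per-nudge, chosen- and
    completed-intervention analysis tables from event logs, and logistic
    regression tooling for tailoring-variable analysis (odds ratios with
    Wald intervals, Benjamini-Hochberg flags, likelihood-ratio tests
    against the null model, Tjur's coefficient of discrimination, variance
    inflation factors, type II analysis of deviance, and Tukey-adjusted
    pairwise contrasts).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    car,
    multcomp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
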