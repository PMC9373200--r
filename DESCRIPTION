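Package: fmams
Title: Simulation and Design Evaluation for Factorial Multi-Arm
    Multi-Stage Platform Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for planning and simulating platform trials that combine
    factorial randomisation with multi-arm multi-stage (MAMS) adaptations.
    Represents a trial as a stage-indexed trajectory of randomisation
    schemes and supports the four design adaptations (stopping a research
    arm for lack of benefit or for efficacy, adding a randomisation, and
    adding an arm to an existing randomisation), deterministic patient-flow
    planning with per-comparison reporting milestones, sequential
    stratified permuted-block randomisation with earlier allocations as
    strata, outcome simulation for binary and time-to-event endpoints with
    an intermediate endpoint for interim futility monitoring,
    group-sequential efficacy boundaries (Haybittle-Peto, O'Brien-Fleming
    and alpha-spending), concurrent-control stage-stratified analysis, and
    Monte-Carlo operating characteristics.
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
    survival
Suggests:
    testthat (>= 3.0.0),
    mvtnorm
Config/testthat/edition: 3
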