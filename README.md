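# fmams

Planning and simulation for **factorial multi-arm multi-stage (MAMS)
platform trials**: trials that run several randomised comparisons
concurrently in the same patients (a factorial design) *and* adapt over
time (stopping research arms for lack of benefit or efficacy, adding new
arms or whole randomisations), under one master protocol.

The package is aimed at trial statisticians designing such hybrids — for
example a trial that starts as a 2×2 factorial of an antiviral (A1 vs A0)
crossed with an immunomodulator (B1 vs B0), and later adds an alternative
antiviral A2 into randomisation A so the scheme becomes
(A1 vs A2 vs A0) × (B1 vs B0).

## What it computes

The trial is represented as a stage-indexed trajectory of randomisation
schemes: a new *stage* opens at every change of scheme, and stages are the
unit of concurrency for analysis. On top of this representation:

* **Patient-flow planning.** Of *n* patients entering a randomisation with
  active arm weights *w*, the comparison of research arm *i* against
  control 0 accrues *n(w<sub>i</sub> + w<sub>0</sub>)/Σw* patients (equal
  weights over *k* arms: *2/k*). `plan_flow()` advances adaptations,
  interims and comparison completions as an event queue and returns the
  stage-by-stage flow table, totals and per-comparison reporting
  milestones.
* **Sequential stratified randomisation.** Permuted blocks within strata
  formed by baseline factors plus all earlier allocations (with a
  "not-randomised" level), including the block-closing rules for adding
  and dropping arms, and reduced-eligibility arm subsets.
* **Outcome simulation.** Binary outcomes from a logistic factorial
  effects model (odds ratios; risk-ratio option), exponential
  time-to-event outcomes with hazard ratios, optional pairwise interaction
  multipliers, an intermediate endpoint whose treatment effects are the
  definitive ones scaled by a concordance parameter ρ, and an optional
  secular trend in baseline risk.
* **Monitoring.** Looks timed by calendar, total patients, or events
  pooled over *all* arms (never per-comparison control counts, which would
  leak effect information — `control_event_audit()` exists for closed DMC
  reports only). Efficacy boundaries: Haybittle-Peto, O'Brien-Fleming
  (constant solved by numerical integration), and Lan-DeMets
  alpha-spending. One-sided futility bounds on the intermediate outcome.
* **Concurrent-control analysis.** Per comparison: patients randomised to
  either arm during stages when both arms were open and who were eligible
  for both; Mantel-Haenszel common odds ratio across stage strata
  (Robins-Breslow-Greenland SE, CMH test) or stage-stratified Cox /
  log-rank; a combined one-regression model with an indicator per research
  intervention plus a stage term; subgroup/interaction analyses.
* **Operating characteristics.** `run_trial()` simulates one trial end to
  end (reproducing the planned flow exactly when stopping is disabled);
  `run_monte_carlo()` aggregates rejection, stopping and sample-size
  distributions with Monte-Carlo standard errors.
* **Planning arithmetic.** Event-rate dilution from effective
  co-interventions (`marginal_event_rate()`), two-proportion and
  Schoenfeld sample sizes, analytic power-loss curves.

## Worked example

The illustrative design: two 2-way randomisations, 3000 patients per
comparison, an interim after 1500 patients at which arm A2 joins
randomisation A.

```r
library(fmams)

design <- make_factorial_design(
  randomisations = list(
    list(id = "A", arms = list(list(id = "A0", role = "control"),
                               list(id = "A1", role = "research"))),
    list(id = "B", arms = list(list(id = "B0", role = "control"),
                               list(id = "B1", role = "research")))),
  targets = 3000, interim_at = 1500, accrual_rate = 100)

design <- apply_adaptation(design,
  adaptation("add_intervention", "A", 1500, arm = list(id = "A2")))

flow <- plan_flow(design)
flow
#> Factorial-MAMS patient-flow plan
#>  stage                        design n_randomised A1_vs_A0 B1_vs_B0 A2_vs_A0
#>      1       (A1 vs A0) × (B1 vs B0)         1500     1500     1500        0
#>      2 (A1 vs A2 vs A0) × (B1 vs B0)         1500     1000     1500     1000
#>      3              (A1 vs A2 vs A0)          750      500        0      500
#>      4                    (A2 vs A0)         1500        0        0     1500
#> Totals: n_randomised=5250  A1_vs_A0=3000  B1_vs_B0=3000  A2_vs_A0=3000
```

Adding A2 costs 2250 extra patients overall. The milestones show when each
comparison can report (cumulative patients randomised), and at 100
patients/month the timeline in months:

```r
reporting_milestones(flow)
#> A1_vs_A0 B1_vs_B0 A2_vs_A0
#>     3750     3000     5250
timeline_export(flow)
#>   comparison start  end complete
#> 1   A1_vs_A0     0 37.5     TRUE
#> 2   B1_vs_B0     0 30.0     TRUE
#> 3   A2_vs_A0    15 52.5     TRUE
```

B reports on schedule at 3000 patients (month 30); A1 needs 750 more
patients (month 37.5) and A2 a further 1500 (month 52.5). Simulating the
trial with a genuinely effective A1 (odds ratio 0.7) and analysing each
comparison against its concurrent controls, stratified by stage:

```r
model <- outcome_model("binary", baseline = 0.3, effects = c(A1 = 0.7))
trial <- run_trial(design, model, seed = 2)
trial
#> Simulated factorial-MAMS trial: 5250 patients, 1495 events, 52.5 time units
#>   A1_vs_A0: complete, null rejected
#>   B1_vs_B0: complete, null not rejected
#>   A2_vs_A0: complete, null not rejected
trial$results[["A1_vs_A0"]]
#> A1_vs_A0: log-OR = -0.3582 (SE 0.0830, 95% CI -0.5208 to -0.1956), z(benefit) = 4.317
```

The estimate recovers log(0.7) = −0.357, and only the truly effective
intervention is declared positive. Two-look O'Brien-Fleming boundaries for
a comparison monitored at half and full information:

```r
efficacy_boundary("obrien_fleming", K = 2, alpha = 0.05)
#> [1] 2.796526 1.977443
```

A thin command-line wrapper is installed with the package
(`inst/cli/fmams.R`): `fmams plan --config design.yaml --out flow.csv`,
`fmams simulate`, `fmams oc`, `fmams boundaries`; the design configuration
file format is documented in `?read_design_config`.

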