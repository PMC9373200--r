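---
title: "Designing and simulating factorial multi-arm multi-stage platform trials"
author: "fmams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and simulating factorial multi-arm multi-stage platform trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmams)
```

## The design problem

A factorial trial runs two or more randomisations concurrently in the same
patients: randomisation A assigns an antiviral agent A1 or its control A0,
randomisation B an immunomodulator B1 or its control B0, and each patient
receives one arm from each. The "at the margins" analysis compares all
patients randomised to A1 with all randomised to A0, pooling over B, so two
questions are answered for roughly the price of one — provided the
interventions do not interact. A multi-arm multi-stage (MAMS) platform
trial, in contrast, gains its efficiency over time: interim looks can stop
recruitment to research arms that are unlikely to succeed (lack of
benefit, usually judged on an information-rich intermediate outcome) or
that are clearly effective (efficacy, judged on the definitive outcome),
and new interventions can join the running protocol.

`fmams` implements the combination: a *factorial-MAMS* design, where a
platform trial carries several concurrent randomisations and each of them
may be adapted mid-course. The package represents the trial as a
stage-indexed trajectory of randomisation schemes: a new **stage** begins
at every change of scheme, and the stage index is the unit of concurrency
for analysis. Four adaptation operators generate the trajectory:

* `stop_lack_of_benefit` / `stop_efficacy` — end randomisation to a
  research arm. In a two-way randomisation this discontinues the whole
  randomisation (subsequent patients all receive its control, or nothing —
  a labelling choice controlled by `deliver_control_after_stop`); in a
  three-or-more-way randomisation only the stopped arm is removed.
* `add_randomisation` — a new two-way randomisation (research vs control)
  appended at the end of the sequence, so earlier randomisations are
  undisturbed.
* `add_intervention` — a research arm inserted into an existing
  randomisation, for interventions that cannot be combined with the arms
  already there (an alternative antiviral joins randomisation A as A2).

`drop_completed` is a fifth, bookkeeping operator: a comparison that has
reached its recruitment target stops randomising, and modelling that as an
explicit adaptation guarantees that *every* scheme change opens a stage —
which the analysis later relies on. Whether to pause a randomisation while
a post-efficacy follow-on comparison is prepared is deliberately out of
scope: an efficacy stop here simply ends the arm (and a two-way
randomisation with it), with the winner optionally folded into standard of
care (`adopt_winner`).

## Deterministic patient flow

`plan_flow()` is the planning twin of the simulator. Under constant
accrual and equal (or rational-weight) allocation, of `n` patients
entering a randomisation with active arm weights `w`, the comparison of
research arm `i` against control `0` accrues `n (w_i + w_0) / sum(w)`
patients — `2/k` under equal weights over `k` arms. The planner advances
an event queue: scheduled adaptations, planned interims, and comparison
completions each close a flow row; completions drop arms or whole
randomisations; recruitment ends when every comparison has reached its
target. With two 2-way randomisations, 3000 patients per comparison and A2
joining at the 1500-patient interim, the plan runs
1500/1500/750/1500 patients across four stages, for 5250 in total, and
reports B at 3000, A1 at 3750 and A2 at 5250 cumulative patients. If a
completion point implies a fractional patient count, the planner rounds
*up* to the next multiple that restores exact allocation — a comparison is
never under-recruited.

Three numerical conventions matter here. Adaptation times are expressed as
cumulative patients randomised (the planner's clock); eligibility
fractions below 1 scale a randomisation's accrual rate; and simultaneous
events at one patient count are processed completions-first, so a
randomisation whose last comparison completes is dropped before a
same-time adaptation is applied. A target that becomes unreachable
(all its contributing arms stopped) is flagged with a warning, never
silently dropped.

## Sequential stratified randomisation

Randomisation is performed sequentially — one randomisation after another,
in position order — with permuted blocks within strata. The stratum for a
randomisation combines the configured baseline factors with the patient's
allocations in all *earlier* randomisations, using a `"not-randomised"`
level for patients who did not enter one of them. Block sizes are a
randomly varying multiple (default 1 or 2) of the weighted arm count, so
imbalance within a stratum is bounded by the open block's per-arm quota.

Adaptations follow the standard block/stratum rules: adding or dropping an
arm of a multi-way randomisation closes that randomisation's open blocks
and opens new ones over the new arm set, while later randomisations keep
their blocks (strata for a new arm simply appear as its patients arrive);
dropping the research arm of a two-way randomisation discontinues it, and
later randomisations use the `"not-randomised"` level for subsequent
patients. Patients eligible for only a subset of a multi-way
randomisation's arms draw from separate block families over that subset,
and are flagged so the analysis restricts them to comparisons entirely
inside their eligible subset. One ambiguity is worth recording: for a
later randomisation's stratum we use a reduced-set patient's *assigned
arm*, not a distinct "reduced-set" level — the assigned arm is what
influences their outcome.

## Outcome model

Patients arrive at a constant rate (spacing `1/rate`; a Poisson process is
available). The definitive outcome is binary or time-to-event. Binary
events follow a logistic factorial model: the linear predictor is
`logit(p0)` plus the log odds ratio of each research intervention the
patient received, plus `log` interaction multipliers for received pairs
(all 1 under the factorial no-interaction default). A risk-ratio
parameterisation is available and makes the event-rate dilution
arithmetic exact. Survival times are exponential with multiplicative
hazard ratios and administrative censoring at the follow-up horizon.

The intermediate outcome used for futility monitoring shares the
definitive outcome's linear predictor scaled by a concordance parameter
`rho` in `[0, 1]` around its own (higher) baseline: `rho = 1` reproduces
the definitive treatment effects, `rho = 0` makes the intermediate outcome
uninformative about treatment. This single-parameter coupling is a
modelling choice — the intermediate endpoint is conceived as lying on the
causal pathway, not as a validated surrogate — and is the simplest model
that lets a design's futility rules be exercised at a chosen informativeness.

A secular trend (a multiplier on the baseline odds, risk or hazard per
unit calendar time, default off) exists for one purpose: making
non-concurrent comparisons genuinely biased, so that the concurrent-control
machinery can be shown to matter. No claim is made that real baseline
drift is geometric.

What the generator deliberately does *not* emulate: staggered site
opening, non-exponential survival, informative censoring or missing
outcomes, delays between an adaptation decision and its implementation.
Passing simulation tests therefore demonstrates the internal consistency
and calibration of the design machinery under idealised accrual, not
robustness to those operational realities.

## Monitoring and boundaries

Interim analyses are timed by total patients, calendar time, or the pooled
event count over **all** arms combined. Per-comparison control-arm event
counts are never used for timing: in a factorial design every comparison
has a different control group, and revealing those counts comparatively
would leak effect information. `control_event_audit()` computes them for
closed Data Monitoring Committee reports only, and the scheduler has no
access to its output by construction.

Efficacy boundaries come in three families: Haybittle-Peto (a fixed
extreme interim threshold, two-sided p* = 0.001 by default, with a
near-nominal final test), O'Brien-Fleming (`c * sqrt(K/k)` with the
constant solved numerically so the total null crossing probability equals
alpha under equal information spacing), and Lan-DeMets alpha-spending
(O'Brien-Fleming-like or Pocock-like spending, boundaries solved look by
look). Crossing probabilities are computed by the classical recursive
numerical integration of the score-scale increments on a 512-point grid,
accurate to about `1e-5`; the unit tests check the recursion against a
bivariate-normal oracle. Futility bounds are one-sided z thresholds per
look on the intermediate outcome, supplied in the monitoring plan
(z-scale rather than effect-scale, and look spacing as configured — both
are conventions the design literature leaves open).

## Concurrent-control analysis

The analysis set for a comparison contains exactly the patients randomised
to one of its two arms *through the randomisation mechanism*, during a
stage in which both arms were open, and eligible for both arms. Patients
given a control by preference, scheme ("all-B0" after a discontinuation)
or reduced-set randomisation are excluded and logged. "Concurrent" is
operationalised as *same stage*: stages exist precisely to mark scheme
changes, and finer calendar matching within a stage is not used.

The primary estimate is stage-stratified: a Mantel-Haenszel common odds
ratio across stage strata (Robins-Breslow-Greenland standard error,
Cochran-Mantel-Haenszel statistic; zero cells handled natively, no
continuity correction in the MH sums; uninformative strata dropped and
logged) for binary outcomes, or a stage-stratified Cox model and log-rank
test for survival. z statistics are oriented so that benefit is positive.
All comparisons can also be fitted jointly in one regression with an
indicator per research intervention plus a categorical stage term
(`combined_model()`); the joint model is main-effects only — the design
rationale for stage adjustment is confounding control, and
stage-by-treatment terms would change the estimand. Subgroup analyses
across another randomisation's arms, with a likelihood-ratio homogeneity
test, are provided by `interaction_analysis()`; after a late-added arm the
new subgroup is necessarily smaller, so these tests are low-powered by
construction.

Planning arithmetic lives in `marginal_event_rate()` (co-intervention
dilution as an exact mixture on the risk-ratio scale; odds-ratio inputs
mapped through the logistic form per allocation cell),
`sample_size_binary()` (textbook two-proportion formula on the diluted
rates, optional Bonferroni), `sample_size_events()` (Schoenfeld) and
`power_loss_curve()`.

## Simulation architecture and problem sizes

`run_trial()` mirrors the planner's event queue, but each advance recruits
real patients through the randomisation engine and simulates their
outcomes in vectorised batches (arms are fixed at allocation, so batching
never looks ahead). Completion triggers use the same deterministic
contribution accounting as the planner, which is why a no-stopping run
realises the planned flow table exactly for any seed — the property the
test suite checks on the illustrative design. Each replicate derives three
named RNG substreams (arrivals, randomisation, outcomes) from its seed, so
extending one module's draws never perturbs another's.

The test suite's Monte-Carlo studies use sizes chosen so that the normal
approximations they check are adequate while the suite stays quick: the
null-calibration study uses a 2×2 design with 800 patients per comparison
(about 280 events per margin) over 2000 replicates; the secular-trend bias
study uses 250 patients per concurrent arm over 2000 replicates (the
concurrent estimator's null distribution is symmetric, so its mean bias is
zero by construction, while the naive all-controls estimator mixes
stage-1 controls at roughly half the odds); power cross-checks use 600
patients per arm at three grid points with 1000 replicates; coverage of
the combined model uses 800-patient trials over 500 replicates.

## Known limitations

Familywise error control is by Bonferroni only; Dunnett-type
correlation-exact multi-arm boundaries are out of scope, as are
response-adaptive randomisation, minimisation, Bayesian analyses, and
re-powered follow-on comparisons after an efficacy stop. Continuous
outcomes are not implemented. The planner treats accrual as constant and
gapless: the calendar cost of preparing an added arm is not modelled.
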