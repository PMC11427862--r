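---
title: "Simulating and analyzing a workplace-stress JITAI deployment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analyzing a workplace-stress JITAI deployment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jitaisim)
```

## The system being modeled

`jitaisim` models a just-in-time adaptive intervention (JITAI) system for
workplace stress: a sensing-driven agent that watches an information
worker's day through everyday work telemetry, estimates momentary stress,
and — when the estimate is high — nudges the worker to perform a brief
(under five minute) stress-reduction microintervention. The package covers
four connected pieces:

1. **a deterministic decision engine** (composite stress score,
   individualized baselines, nudge-gating rules, an engagement-flow state
   machine, and random intervention selection from a fixed catalog);
2. **a discrete-event deployment simulator** that generates a full cohort,
   its telemetry, EMA self-reports and nudge-response behavior, emitting a
   time-ordered event log;
3. **a feature builder** that reconstructs the three analysis tables
   (per-nudge, chosen-intervention, completed-intervention) from any event
   log in the documented schema; and
4. **logistic outcome models** for tailoring-variable analysis, reported
   as odds ratios with Wald 95% intervals, Benjamini-Hochberg flags,
   likelihood-ratio tests against the null model, Tjur's R², variance
   inflation factors, type II analysis of deviance, and Tukey-adjusted
   pairwise contrasts.

Because no deployment data of this kind are public, the simulator is a
first-class component: it encodes, as generative truth, the coefficient
sets and descriptive statistics reported for a real 43-participant,
4-week deployment, so that the whole pipeline — engine, features, models —
is testable end to end, including recovery of the generating odds ratios.

## The composite stress score and baselines

The engine's stress estimate is the arithmetic mean of five components,
each clipped to $[0,1]$: emails received so far today, total meetings
scheduled today, fraction of the workday elapsed, a facial-expression
score (corrugator + lip depressor − zygomatic major), and heart rate. The
published system's exact normalizations are not available, so the package
uses clipped min–max transforms with documented defaults (emails 0–20/day,
meetings 0–8/day, facial ±3 a.u., heart rate 55–110 bpm). These are
monotone and bounded; `compute_stress_score()` is monotone nondecreasing
in every raw signal, and the score equals the component mean to machine
precision.

Each participant's baselines — one threshold on the score scale, one on
the 1–5 EMA scale — are the means of their week-one observations
(`learn_baseline()`); during week one the defaults sit at the midpoints
(0.5 and 3). Baselines are frozen after week one; there is no rolling
update.

## Gating rules and the stress trigger

A nudge is sent only if, in order: the time is within working hours
(half-open $[\text{start}, \text{end})$); no user-scheduled intervention
is pending later that day; no intervention was completed in the past 60
minutes; no nudge was sent in the past 120 minutes; fewer than 4 nudges
have been sent that day; and the stress trigger fires. The engine
evaluates on an exact five-minute tick aligned to the workday start.

Two points were genuinely open and are resolved as package design
choices, both switchable in `gating_rules()`:

* **Trigger combination.** The trigger defaults to AND: the computed
  score must exceed its baseline *and* a fresh EMA must exceed its
  baseline. With OR, the deterministic fraction-of-day component keeps
  every afternoon's score above the week-one mean, which saturates the
  120-minute cooldown (≈2.9 nudges per participant-day, ≈2,500 per
  study — well above the reported deployment volume) and spreads nudges
  uniformly over the afternoon. AND reproduces both the deployment's
  total nudge volume (≈1,100–1,200 under default conditions) and its
  documented clustering of nudges shortly after EMAs. An EMA is treated
  as "fresh" for 90 minutes — the expected gap between five EMAs over an
  eight-hour day — i.e. the latest self-report is the system's current
  stress estimate until roughly the next one arrives.
* **User-scheduled fires.** A nudge fired at a user-postponed time
  bypasses the two cooldown rules (the user explicitly asked for that
  time) but still respects working hours and counts toward the daily cap
  and toward subsequent cooldowns. Without the exemption, most
  postponements — drawn less than two hours ahead — would die at fire
  time, and the rescheduled share of nudges would fall to roughly half
  the observed fraction. Consequently, on a simulated trajectory the
  guaranteed 120-minute spacing applies to algorithm-triggered (JIT)
  nudges; a user-scheduled fire may follow the preceding nudge sooner.

## The engagement flow

`new_flow()`/`step_flow()` implement the interaction state machine: a
nudge may be postponed to a later time the same day (the rescheduled
nudge is flagged as such), expire after exactly 30 minutes of inactivity,
or proceed through category choice → pre-intervention stress report →
intervention → done → rating → post-intervention stress report. Illegal
transitions raise errors naming the state and event. A flow is *engaged*
as soon as `done` is reached, regardless of whether the rating or
post-stress prompts follow. `select_intervention()` draws uniformly
without replacement within the chosen category (18 items per category)
and resets the per-category served set on exhaustion.

## What the simulator generates — and what it does not

Participant traits are clipped normals matched to the deployment cohort's
means, SDs and instrument ranges; gender and collapsed age-group
marginals match the reported 29/14 and 14/18/11 splits in expectation.
Telemetry counts are Poisson for near-equidispersed channels (meetings
0.30 per half-hour, self events 0.12, ad hoc calls 0.04) and negative
binomial, moment-matched to the reported means and SDs, for overdispersed
ones (emails sent/read, chats, attention signals capped at 5,705).
Sensed signals are simple but structured: cumulative email arrivals, a
fixed daily meeting total, a linear fraction-of-day ramp, white-noise
facial scores, and an AR(1) heart-rate series.

Behavioral outcomes are drawn from logistic models whose coefficients are
the natural logs of the odds ratios estimated on the real deployment.
Three modeling choices deserve emphasis:

* **Category choice** is a single multinomial over the three
  category-model linear predictors (a softmax of utilities). The source
  analysis fit three separate binary models that are not jointly
  coherent; the softmax is the documented approximation.
* **The improvement intercept** corresponds to an odds ratio below
  printable precision, so it is calibrated numerically
  (`calibrate_intercept()`) to reproduce the observed marginal
  improvement rate (150/521); all slope coefficients are taken as
  printed. Liking is derived from the rating (`rating ≥ 4`), not drawn
  from its own model, to avoid circularity with the improvement model,
  which uses the rating as a covariate. Post-intervention stress is set
  consistently with the improvement draw (reduction 1–3 when improved,
   0 or −1 otherwise, clipped to the 1–5 scale).
* **Two covariates are circular at generation time.** Engagement
  skewness and the per-slot nudge probability are post-hoc features of
  the whole log. During a simulated deployment the truth models use a
  latent per-participant engagement-tendency trait and the expected slot
  share (6.25%); the feature builder later recomputes both empirically.
  The parameter-recovery experiments (`simulate_nudge_records()`,
  `simulate_completed_records()`) instead generate these covariates
  directly and fit on exactly what was generated, so recovery is clean.

Known limitations. Pre-intervention stress is drawn from a fixed
distribution (mean 2.14), uncorrelated with the momentary score, so the
real deployment's selection effect — engaged moments showing *higher*
self-reports than the average nudge moment — is not emulated; under the
AND trigger the at-nudge EMA is mechanically at least 2, so the simulated
at-nudge mean sits slightly above the pre-intervention mean rather than
below it. What the simulator does reproduce is the stress-reduction
ordering (post-intervention mean below pre-intervention mean). Real
telemetry is also autocorrelated within and across windows and
participants in ways the independent draws here are not; passing tests
demonstrate the pipeline's correctness under the stated generative
conditions, not fidelity to any particular organization's data.

## Calibration of the study conditions

Default generator parameters are fixed at the deployment's reported
conditions: 43 participants, 4 weeks, 5 EMAs per workday (minimum spacing
30 minutes, response probability 0.9), 09:00–17:00 workdays, Poisson /
negative-binomial telemetry matched to the per-nudge descriptives, a
postponement probability of 0.19 (so the rescheduled share of nudges is
≈16%), an abandon-after-choice probability of 0.085 and a
post-report probability of 0.925 (matching the chosen- and
completed-table attrition). Under these defaults a full simulation yields
on the order of 1,100–1,200 nudges, inside the ±40% band around the
reported 1,585; per-nudge covariate means land within ±30% of the
reported values. A detail worth noting: the per-slot nudge-probability
covariate averages higher in simulated tables (≈12%) than the reported
6% because simulated nudges concentrate in fewer distinct slots per
participant; its generating coefficient (OR 1.02 per percentage point) is
small, so this has negligible effect elsewhere.

## The outcome models

`fit_model()` fits maximum-likelihood logistic regressions of the five
outcomes (engagement over all nudges; the three category choices and
engagement-after-choice over chosen interventions; liking and improvement
over completed interventions) with the reference levels of the source
analysis (age 18–35, man, system trigger, distract, conversation, at
desk). Attention signals enter divided by 2,000 and nudge probability in
percent. Chat counts are built but excluded from every default formula.
The engagement design has 21 non-intercept parameters; the enumerated
improvement design has 29.

Inference outputs follow the field's standard toolchain: Wald intervals
(symmetric on the log-odds scale), Benjamini–Hochberg flags within each
model's predictor family (intercept excluded), the deviance difference
against the intercept-only model, Tjur's coefficient of discrimination,
per-column VIFs computed from the definition $1/(1-R^2_j)$ (exact
collinearity reported as infinite), type II analysis of deviance via
`car::Anova`, and Tukey-style family-wise contrasts via `multcomp::glht`
(single-step multivariate-normal adjustment — studentized-range tables
are a linear-model construct and are not used).

Separation is handled loudly by default: rank deficiency, non-convergence
and quasi-separation (any |coefficient| > 15 or fitted probabilities at
the boundary) raise errors rather than returning unstable estimates.
Because the generative truth makes near-separation a real event at
study-sized samples (the improvement model's *outside*-location odds
ratio of 0.23 applies to only ≈5% of a few hundred completed rows),
`fit_model(..., separation = "firth")` offers Firth's bias-reduced
penalized likelihood as a finite-estimate fallback, and `run_pipeline()`
uses it so that a full study-sized run always completes; Firth fits
report coefficients, Wald intervals, a penalized LR test, Tjur's R² and
VIFs, but no type II or Tukey decompositions.

## Numerical and engineering choices

* Timestamps are timezone-naive study-local times stored as UTC;
  intervals are half-open everywhere; half-hour slots are floors to
  :00/:30.
* One global seed fans out to per-participant substreams
  (`sample.int`-drawn seeds), so growing the cohort preserves existing
  participants, and every simulation is byte-identical under a repeated
  `(config, seed)`.
* Skewness uses the Fisher–Pearson $g_1 = m_3 / m_2^{3/2}$ on the
  hour-of-day values of engaged interventions; fewer than three values or
  zero variance yield 0 (with a warning) so every participant remains
  usable as a covariate row.
* The per-slot nudge probability is computed per participant (not
  pooled), matching its reported per-participant scale.
* EMA prompts are placed by a uniform-with-minimum-gap construction
  (sorted uniforms on the day minus the total spacing, gaps re-inserted).
* The problem sizes used by the test suite and the acceptance script —
  50,000-record recovery runs, a single full 43×4 simulation, 500-run
  null-calibration loops — were chosen so that Monte Carlo error is small
  against every tolerance being checked.

## Interfaces

The package's functions are its interface: `run_pipeline(config, seed)`
drives simulate → features → fit → summarize and can write the event log
(JSONL), the three tables (CSV), model results (JSON) and a run manifest
to a directory. `write_event_log()`/`read_event_log()` round-trip the
documented one-event-per-line JSONL schema, so externally produced logs
in the same schema can be analyzed with `build_model_tables()` and
`fit_model()` directly. Configuration is a nested list mirrored in YAML
(`read_config()`), with unspecified entries keeping their defaults.
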