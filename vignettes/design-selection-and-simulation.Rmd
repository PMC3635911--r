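---
title: "Choosing and simulating randomised designs for small populations"
author: "smalltrial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choosing and simulating randomised designs for small populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smalltrial)
```

## The problem

When a disease is rare — or the eligible population is otherwise small, as
in paediatrics — the conventional two-arm parallel-group trial is often
infeasible: it needs more patients than can be recruited. A family of
randomised comparative designs exists that trades structural assumptions
(outcome reversibility, disease stability, rapid observable response) for
efficiency or for ethically attractive properties such as less time on
placebo. Choosing among them is not simple, because each design's
advantages are bought with specific requirements.

`smalltrial` does two things:

1. it encodes a catalogue of twelve randomised comparative designs and a
   five-node decision algorithm that maps a disease–treatment–outcome
   scenario onto the subset of designs that remain feasible; and
2. it provides a Monte-Carlo simulator for every catalogued design, so the
   shortlisted candidates can be compared quantitatively — power, type-I
   error, person-time on placebo, allocation behaviour — before one is
   chosen.

## The decision algorithm

The five decision nodes are applied in a fixed order:

1. **Outcome reversibility.** Designs that re-expose patients or withdraw
   an effective treatment (cross-over, Latin square, N-of-1, randomised
   withdrawal, three-stage, early escape, delayed start) need an outcome
   that can return to its pre-treatment state.
2. **Response speed.** "Fast" means observable within up to a few weeks.
   Urn-adaptive randomisation and early escape react to each patient's
   observed outcome, so their mechanics need fast responses even when
   placebo-sparing is not requested.
3. **Minimising time on placebo.** Seven designs spare placebo exposure.
   Four of them (randomised withdrawal, early escape, three-stage,
   adaptive randomisation) do so only by reacting quickly to observed
   responses, so on the slow branch the placebo-sparing set reduces to
   the three designs in which everyone is eventually treated by
   construction: delayed start, randomised placebo-phase, stepped wedge.
4. **All patients on active treatment by the end.** Exactly those three
   designs guarantee it.
5. **Comparison basis.** Cross-over, Latin square and N-of-1 compare
   within patient; the rest between patients.

Because the nodes act by set intersection, the feasible set is independent
of their order; the order only determines which node an exclusion is
attributed to. The engine is checked against an independent brute-force
attribute filter on all 48 possible contexts, and reproduces the four
published walkthroughs (all 12 feasible; 7 after requiring placebo
minimisation; the {delayed start, placebo phase, stepped wedge} triple on
the slow branch; 5 designs for an irreversible, fast outcome).

Two deliberate scope choices. First, *stable chronic disease* is stored as
a profile attribute but not used as a node; it is advisory, as is the
binary-outcome requirement. Second, the engine reproduces the algorithm's
output only; contextual judgements (for instance, that a placebo-phase
design is meaningless when both arms are active treatments) are surfaced
as a caveat on every report rather than encoded as rules, since they
depend on information the five nodes do not carry.

## Response models

The paper-level designs need three outcome families, and the package
generates all patient-level data itself:

* **Binary responder model** — Bernoulli success per patient-period with
  arm-specific probabilities; optional first-order carry-over adds a
  probability shift (clipped to [0, 1]) when the previous period was
  active. Carry-over is deliberately minimal: one-period memory, additive,
  default 0.
* **Score trajectories** — linear-in-time scores (units: points/week) with
  treatment-dependent slopes, an immediate symptomatic offset under
  active treatment, patient-level baselines, and within-patient
  equicorrelation `rho` induced by a shared random intercept. Higher
  scores mean worse disease, as with clinical rating scales.
* **Response latencies** — piecewise-exponential time-to-response:
  hazard `hazard_untreated` before the (randomised) treatment start and
  `hazard_treated` after, sampled by inverting the cumulative hazard.

All generators are pure functions of (model, inputs, seed) and
bit-reproducible. What they do *not* model — by design — is dropout,
missing data, covariates, and non-linear disease trajectories; passing
tests therefore demonstrate internal calibration and correctness of the
machinery, not robustness of any design to those real-data features.

## Simulators and their test statistics

The source material names no test statistics, so the package uses the
simplest tests with known calibration, all configurable through the
scenario's `alpha`:

| design | primary analysis |
|---|---|
| parallel | pooled two-proportion z (binary) or Welch t (continuous) |
| factorial | pooled-variance t on factor margins; cell-contrast t for interaction |
| crossover | two-sample t on period half-differences between sequence groups |
| Latin square | paired t, tested treatment vs placebo, within patient |
| N-of-1 | paired t over the within-pair measurement differences |
| delayed start | three gatekept tests (below) |
| placebo phase | log-rank across delay groups, censored at horizon |
| stepped wedge | cluster/period fixed-effect linear model on cluster-period means |
| withdrawal | two-proportion z on relapse among randomised responders |
| early escape | two-proportion z on cumulative failure at horizon |
| three-stage | Fisher combination (chi-square, 2k df) of three stage z-tests |
| adaptive urn | two-proportion z on final arm outcomes |

The delayed-start design tests, sequentially (each only if the previous
passed): superiority at the end of the placebo phase; superiority of early
over delayed start at the end of the trial; and non-inferiority of the
early group's second-period slope at a user-supplied margin
(score-units/week, one-sided at `alpha/2`). A purely symptomatic effect
(offset only) passes the first test but produces a null end-of-study
contrast, which is exactly the property that makes the design able to
separate symptomatic from disease-modifying activity.

The urn module implements the randomised play-the-winner rule (success on
arm *i* adds one type-*i* ball; failure adds one ball partitioned over the
*other* arms in proportion to their current counts — which forces
fractional counts for three or more arms) and the drop-the-loser rule
(failure removes a ball, floored at zero; drawing an immigration ball adds
one ball of every treatment type and triggers a redraw). The failure
partition is read as excluding the treated arm's own balls; other
conventions exist in the literature, and the enumeration oracle in the
test suite pins the implemented one. Outcomes are assumed observed before
the next patient arrives; generalisations for delayed responses are out of
scope. Default initial compositions are one ball per arm, plus one
immigration ball for drop-the-loser.

Every simulator accounts person-time exactly: placebo + active +
unexposed follow-up equals total follow-up in each replicate, and the
three all-patients-treated designs report a proportion ever on active
treatment of exactly 1, matching their catalogue flag.

## Numerical and calibration choices

* **Seeding.** Each simulator seeds its own RNG from the scenario seed and
  restores the caller's RNG state, so summaries are bit-reproducible and
  independent of execution order. `compare_designs()` derives one child
  seed per design from the master seed and the design's registry
  position.
* **Degenerate replicates.** Replicates in which a required group is empty
  (no responders to randomise, an arm never allocated, no events to
  compare) are non-informative: they are excluded from the rejection-rate
  denominator and counted. A three-stage stage with no evaluable patients
  contributes p = 1, conservatively, and is flagged.
* **Calibration checkpoints.** Discreteness makes the exact size of any
  proportion test oscillate around its nominal level (e.g. the pooled
  z-test has exact size 0.0569 at p = 0.5 with 50 per arm, and 0.0498 at
  p = 0.3 — values obtained by exhaustive binomial enumeration). The
  calibration tests therefore check simulators against *exactly
  enumerated* rejection probabilities where enumeration is feasible
  (parallel, early escape, withdrawal), and run nominal-level checks at
  operating points where the reference test is itself nominal; the
  log-rank check uses 120 patients because the log-rank statistic is
  visibly anti-conservative at 40. Problem sizes in the suite (50 per arm
  for binary nulls, 20 patients for crossover, 6 clusters × 5 steps, 150
  per arm for the three-stage pipeline, 10000 replicates for calibration
  runs) were chosen once as realistic for the small-trial setting while
  keeping asymptotic test references accurate.
* **Tie-breaks.** An odd number of withdrawal responders sends the extra
  patient to a coin-flipped arm; stepped-wedge clusters are spread over
  steps round-robin when there are more clusters than steps.

## Known limitations

* The feasibility attributes reconstruct the published algorithm's
  input→output behaviour from its worked examples; the exact internal
  branching of the original decision tree is not printed anywhere, so any
  attribute assignment reproducing the same mappings is observationally
  equivalent.
* The closed-form normal-approximation power formula for two proportions
  is accurate only to ~0.005 at 25 patients per arm, where the exact
  power of the z-test is 0.9722 versus 0.9673 for the approximation (both
  by enumeration); comparisons between the simulator and the closed form
  at small n reflect the approximation, not the simulator.
* Within-patient simulators draw period differences from the model's
  implied difference distribution rather than assembling full visit-level
  series; this is exact for the analyses used but means per-visit export
  is only available from the trajectory generator, not from those
  simulators.
* No dropout, missingness, covariates, interim monitoring, Bayesian or
  sequential methods; the comparison table informs a choice, it does not
  make one.
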