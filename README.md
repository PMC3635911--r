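# smalltrial

Design selection and Monte-Carlo evaluation of randomised trial designs
for small populations — rare diseases, paediatrics, and any setting where
a conventional parallel-group trial cannot recruit enough patients.

Statisticians and trialists planning such studies face a catalogue of
alternative randomised comparative designs — cross-over, Latin square,
N-of-1, factorial, delayed start, randomised placebo-phase, stepped
wedge, randomised withdrawal, early escape, three-stage, and urn-based
response-adaptive randomisation — each buying efficiency or reduced
placebo exposure with structural requirements on the disease, treatment
and outcome. `smalltrial` makes that choice systematic:

* a **machine-readable design catalogue** (twelve profiles with their
  selection-relevant attributes, advantages and limitations);
* a **decision algorithm** over five nodes — outcome reversibility,
  response speed (fast = observable within up to a few weeks),
  placebo-time minimisation, all-patients-treated-by-trial-end, and
  intra- vs inter-patient comparison — returning the feasible subset
  with the excluding node for each rejected design;
* **simulators for every design**, driven by three synthetic response
  families (Bernoulli responders; score trajectories with
  treatment-dependent slopes *β*<sub>active</sub>, *β*<sub>placebo</sub>
  (points/week), symptomatic offset and within-patient correlation *ρ*;
  piecewise-exponential response latencies with hazards
  *λ*<sub>untreated</sub>, *λ*<sub>treated</sub>), reporting rejection
  rate ± Monte-Carlo s.e., person-time on placebo/active treatment,
  proportion of patients ever on active treatment, and allocation;
* the **urn models** of response-adaptive randomisation: randomised
  play-the-winner (success on arm *i* adds a type-*i* ball; failure adds
  one ball split over the other arms in proportion to their counts) and
  drop-the-loser (failures remove balls; immigration balls replenish all
  arms and trigger a redraw);
* **Fisher's method** for the three-stage design: *X* = −2 Σ log
  *p*<sub>i</sub> referred to χ²(2k), so three stage p-values of 0.05
  combine to 0.0063;
* a **comparison table** and a **command-line interface** binding it all
  together.

## Worked example

A chronic disease with a reversible outcome, a slow response
(> a few weeks), and an ethical requirement to minimise time on placebo:

```r
library(smalltrial)

ctx <- decision_context(outcome_reversible = TRUE, response_speed = "slow",
                        minimize_placebo_time = "required")
select_designs(ctx)
#> Design selection: 3 of 12 designs feasible
#>   feasible: delayed_start, placebo_phase, stepped_wedge
#>   excluded:
#>     early_escape (node: response_speed)
#>     adaptive_randomization (node: response_speed)
#>     parallel (node: placebo_minimization)
#>     ...
```

Only the three designs in which every patient is eventually treated
survive: placebo-sparing by *reacting* to responses (withdrawal, early
escape, three-stage, adaptive) needs fast outcomes. Now compare the
shortlist quantitatively under one shared scenario:

```r
template <- list(
  binary = binary_model(c(active = 0.8, placebo = 0.3)),
  trajectory = trajectory_model(baseline_mean = 50, slope_active = 0.4,
                                slope_placebo = 1.0, residual_sd = 8,
                                rho = 0.7, symptomatic_offset = -4),
  latency = latency_model(0.02, 0.3),
  n_per_arm = 25)
compare_designs(ctx, template, seed = 42, n_reps = 2000)
#> Design comparison (fingerprint 09afa5a1)
#>         design simulable rejection_rate rejection_se
#>  delayed_start      TRUE         0.9935     0.001797
#>  placebo_phase      TRUE         1.0000     0.000000
#>  stepped_wedge      TRUE         0.6195     0.010856
#>  mean_person_time_on_placebo proportion_ever_active mean_n_randomized
#>                        600.0                      1                50
#>                        315.1                      1                50
#>                        512.0                      1                48
```

Under this scenario (a strongly effective, partly symptomatic treatment,
50 patients) the placebo-phase design detects the effect in every
replicate while accruing roughly half the placebo person-time of the
delayed-start design; the stepped wedge, at six clusters, is
underpowered. All three treat every patient by trial end
(`proportion_ever_active = 1`). The rejection rate is each design's own
primary analysis at α = 0.05; person-time is in week-equivalents of the
scenario's period lengths.

The same is available from a shell:

```sh
Rscript inst/cli/smalltrial select --reversible yes --response slow --minimize-placebo
Rscript inst/cli/smalltrial simulate --design parallel --config scenario.yaml --reps 10000 --seed 42
Rscript inst/cli/smalltrial registry --export --out registry.json
```

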