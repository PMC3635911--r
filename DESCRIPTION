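Package: smalltrial
Title: Design Selection and Simulation for Small-Population Randomised Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for choosing and evaluating randomised trial designs when
    few patients are available, as in rare diseases and paediatric research.
    Provides a machine-readable catalogue of twelve randomised comparative
    designs (parallel, factorial, cross-over, Latin square, N-of-1, delayed
    start, randomised placebo-phase, stepped wedge, randomised withdrawal,
    early escape, three-stage, and response-adaptive urn randomisation), a
    decision algorithm that maps a disease-treatment-outcome scenario onto
    the subset of feasible designs through five decision nodes, and
    Monte-Carlo simulators for every catalogued design so that candidate
    designs can be compared on power, type-I error, time on placebo, and
    allocation properties. Includes response-adaptive urn models
    (randomised play-the-winner and drop-the-loser with immigration balls),
    Fisher's method for combining stage p-values, synthetic patient-response
    generators (binary responders, score trajectories with
    treatment-dependent slopes, response latencies), and a command-line
    interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite, yaml, survival
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
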