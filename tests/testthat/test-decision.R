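test_that("the four case-study scenarios reproduce the published walkthroughs", {
  # reversible outcome, rapid response: every design remains possible
  all_open <- select_designs(decision_context(TRUE, "fast"))
  expect_setequal(all_open$feasible, design_names())
  expect_equal(nrow(all_open$excluded), 0L)

  # ... and requiring minimal placebo time leaves seven designs
  seven <- select_designs(decision_context(TRUE, "fast",
                                           minimize_placebo_time = "required"))
  expect_length(seven$feasible, 7L)
  expect_setequal(seven$feasible,
                  c("delayed_start", "placebo_phase", "stepped_wedge",
                    "randomized_withdrawal", "early_escape", "three_stage",
                    "adaptive_randomization"))

  # reversible but slow response with minimal placebo time: only the three
  # designs whose placebo-sparing does not rely on reacting to outcomes
  slow <- select_designs(decision_context(TRUE, "slow",
                                          minimize_placebo_time = "required"))
  expect_setequal(slow$feasible,
                  c("delayed_start", "placebo_phase", "stepped_wedge"))

  # irreversible outcome, rapid response: five designs, i.e. four besides
  # urn-adaptive randomisation
  irr <- select_designs(decision_context(FALSE, "fast"))
  expect_length(irr$feasible, 5L)
  expect_true("adaptive_randomization" %in% irr$feasible)
  expect_length(setdiff(irr$feasible, "adaptive_randomization"), 4L)
})

test_that("an intra-patient preference keeps exactly the within-patient designs", {
  sel <- select_designs(decision_context(TRUE, "fast",
                                         comparison_preference = "intra_patient"))
  expect_setequal(sel$feasible, c("crossover", "latin_square", "n_of_1"))
})

test_that("the engine equals brute-force attribute filtering on all 48 contexts", {
  grid <- expand.grid(rev = c(TRUE, FALSE), speed = c("fast", "slow"),
                      minpl = c("indifferent", "required"),
                      allact = c("indifferent", "required"),
                      comp = c("indifferent", "intra_patient", "inter_patient"),
                      stringsAsFactors = FALSE)
  expect_equal(nrow(grid), 48L)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    sel <- select_designs(decision_context(g$rev, g$speed, g$minpl,
                                           g$allact, g$comp))
    expect_identical(sel$feasible,
                     oracle_select(g$rev, g$speed, g$minpl, g$allact, g$comp),
                     info = paste(unlist(g), collapse = "/"))
    # partition invariant: feasible and excluded split the catalogue
    expect_setequal(c(sel$feasible, sel$excluded$design), design_names())
    expect_length(intersect(sel$feasible, sel$excluded$design), 0L)
  }
})

test_that("tightening any constraint never enlarges the feasible set", {
  base_grid <- expand.grid(rev = c(TRUE, FALSE), speed = c("fast", "slow"),
                           stringsAsFactors = FALSE)
  for (i in seq_len(nrow(base_grid))) {
    g <- base_grid[i, ]
    loose <- select_designs(decision_context(g$rev, g$speed))$feasible
    for (tight in list(
      decision_context(g$rev, g$speed, minimize_placebo_time = "required"),
      decision_context(g$rev, g$speed, all_active_at_end = "required"),
      decision_context(g$rev, g$speed, comparison_preference = "intra_patient"),
      decision_context(g$rev, g$speed, comparison_preference = "inter_patient"))) {
      expect_true(all(select_designs(tight)$feasible %in% loose))
    }
  }
})

test_that("exclusions are attributed to the first node that removes a design", {
  sel <- select_designs(decision_context(FALSE, "slow",
                                         minimize_placebo_time = "required"))
  ex <- sel$excluded
  expect_equal(ex$node[ex$design == "crossover"], "reversibility")
  # adaptive randomisation needs reversible outcomes? no — it is removed by
  # the response-speed node on the slow branch
  expect_equal(ex$node[ex$design == "adaptive_randomization"],
               "response_speed")
})

test_that("selection reports annotate feasible designs and flag empty sets", {
  sel <- select_designs(decision_context(FALSE, "fast"))
  rep_ <- explain_selection(sel)
  expect_false("crossover" %in% names(rep_$feasible))
  expect_equal(rep_$excluded$node[rep_$excluded$design == "crossover"],
               "reversibility")
  # the cross-over profile carries the stable-chronic-disease limitation
  expect_true(any(grepl("Stable chronic",
                        design_profile("crossover")$limitations[[1]])))

  full <- explain_selection(select_designs(decision_context(TRUE, "fast")))
  expect_length(full$feasible, 12L)
  expect_equal(nrow(full$excluded), 0L)

  empty <- explain_selection(select_designs(
    decision_context(FALSE, "fast", comparison_preference = "intra_patient")))
  expect_length(empty$feasible, 0L)
  expect_true(any(grepl("no catalogued design", empty$caveats)))
})
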