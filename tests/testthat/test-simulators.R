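# shared fixtures ------------------------------------------------------------

null_traj <- trajectory_model(baseline_mean = 50, baseline_sd = 5,
                              residual_sd = 8, rho = 0.7)

conservation_ok <- function(s) {
  expect_equal(s$mean_person_time_on_placebo + s$mean_person_time_on_active +
                 s$mean_person_time_unexposed,
               s$total_follow_up, tolerance = 1e-9,
               info = s$design)
}

test_that("Fisher's method reproduces its chi-square oracle", {
  expect_equal(fisher_combine(c(1, 1, 1)), 1)
  expect_equal(fisher_combine(0.05), 0.05, tolerance = 1e-12)
  # frozen oracle: pchisq(-2*3*log(0.05), df = 6, lower.tail = FALSE)
  expect_equal(fisher_combine(c(0.05, 0.05, 0.05)), 0.0062965,
               tolerance = 1e-4)
  expect_error(fisher_combine(c(0.5, 0)), "in \\(0, 1]")
  expect_error(fisher_combine(1.2), "in \\(0, 1]")
  expect_error(fisher_combine(numeric(0)), "in \\(0, 1]")
})

test_that("parallel-group rejection matches exact enumeration, null and power", {
  reps <- 4000
  # null at an operating point where the score test is nominal
  s0 <- simulate_parallel(trial_scenario(
    "parallel", binary = binary_model(c(active = 0.3, placebo = 0.3)),
    n_per_arm = 50, n_reps = reps, seed = 4242))
  expect_true(within_3se(s0$rejection_rate,
                         oracle_two_prop_size(50, 50, 0.3, 0.3), reps))
  # the test's exact (slightly anti-conservative) size at p = 0.5 is also
  # reproduced -- a sharper check than comparing to nominal alpha
  s5 <- simulate_parallel(trial_scenario(
    "parallel", binary = binary_model(c(active = 0.5, placebo = 0.5)),
    n_per_arm = 50, n_reps = reps, seed = 4243))
  expect_true(within_3se(s5$rejection_rate,
                         oracle_two_prop_size(50, 50, 0.5, 0.5), reps))
  # power against the exact enumerated value
  sp <- simulate_parallel(trial_scenario(
    "parallel", binary = binary_model(c(active = 0.8, placebo = 0.3)),
    n_per_arm = 25, n_reps = reps, seed = 4244))
  expect_true(within_3se(sp$rejection_rate,
                         oracle_two_prop_size(25, 25, 0.8, 0.3), reps))
  # structural accounting
  expect_equal(sp$proportion_ever_active, 0.5)
  conservation_ok(sp)
  expect_error(simulate_parallel(trial_scenario(
    "parallel", binary = binary_model(c(active = 0.5, placebo = 0.5)),
    n_patients = 50, ratio = c(1, 0))), "positive")
})

test_that("continuous-outcome parallel comparison is calibrated", {
  s <- simulate_parallel(trial_scenario(
    "parallel", trajectory = null_traj, n_per_arm = 20, horizon_weeks = 24,
    n_reps = 4000, seed = 4245))
  expect_true(within_3se(s$rejection_rate, 0.05, 4000))
})

test_that("factorial margins are calibrated and match parallel power at full n", {
  reps <- 4000
  s0 <- simulate_factorial(trial_scenario(
    "factorial", n_per_cell = 13, effect_a = 0, effect_b = 0,
    interaction = 0, sd = 1, n_reps = reps, seed = 4246))
  expect_true(within_3se(s0$rejection_rate, 0.05, reps))
  expect_true(within_3se(s0$extras$rejection_rate_b, 0.05, reps))
  expect_true(within_3se(s0$extras$rejection_rate_interaction, 0.05, reps))
  conservation_ok(s0)

  # an A-only effect: the factor-A margin uses the full sample, so its power
  # matches a parallel trial of the same total size and effect
  sA <- simulate_factorial(trial_scenario(
    "factorial", n_per_cell = 13, effect_a = 0.8, effect_b = 0,
    interaction = 0, sd = 1, n_reps = reps, seed = 4247))
  tm <- trajectory_model(symptomatic_offset = 0.8, residual_sd = 1)
  sPar <- simulate_parallel(trial_scenario(
    "parallel", trajectory = tm, n_per_arm = 26, horizon_weeks = 1,
    n_reps = reps, seed = 4248))
  expect_lt(abs(sA$rejection_rate - sPar$rejection_rate), 0.05)

  # a strong qualitative interaction is detected as n grows
  small <- simulate_factorial(trial_scenario(
    "factorial", n_per_cell = 6, effect_a = 0, effect_b = 0,
    interaction = 2, sd = 1, n_reps = 1500, seed = 4249))
  large <- simulate_factorial(trial_scenario(
    "factorial", n_per_cell = 40, effect_a = 0, effect_b = 0,
    interaction = 2, sd = 1, n_reps = 1500, seed = 4250))
  expect_gt(large$extras$rejection_rate_interaction,
            small$extras$rejection_rate_interaction)
  expect_gt(large$extras$rejection_rate_interaction, 0.95)
})

test_that("crossover analysis is calibrated and beats parallel at equal total n", {
  reps <- 4000
  s0 <- simulate_within_patient(trial_scenario(
    "crossover", trajectory = null_traj, n_patients = 20,
    n_reps = reps, seed = 4251), "crossover")
  expect_true(within_3se(s0$rejection_rate, 0.05, reps))
  conservation_ok(s0)
  expect_equal(s0$proportion_ever_active, 1)

  eff <- trajectory_model(baseline_mean = 50, residual_sd = 8, rho = 0.7,
                          symptomatic_offset = -5)
  sx <- simulate_within_patient(trial_scenario(
    "crossover", trajectory = eff, n_patients = 20, n_reps = 2000,
    seed = 4252), "crossover")
  sp <- simulate_parallel(trial_scenario(
    "parallel", trajectory = eff, n_per_arm = 10, horizon_weeks = 4,
    n_reps = 2000, seed = 4253))
  expect_gt(sx$rejection_rate, sp$rejection_rate)
})

test_that("unwashed carry-over attenuates the crossover treatment contrast", {
  carry <- trajectory_model(residual_sd = 4, rho = 0.5,
                            symptomatic_offset = -4, carryover = -3)
  with_wash <- simulate_within_patient(trial_scenario(
    "crossover", trajectory = carry, n_patients = 16, washout = TRUE,
    n_reps = 2000, seed = 4254), "crossover")
  without <- simulate_within_patient(trial_scenario(
    "crossover", trajectory = carry, n_patients = 16, washout = FALSE,
    n_reps = 2000, seed = 4254), "crossover")
  expect_gt(with_wash$rejection_rate, without$rejection_rate)
})

test_that("Latin square layouts are balanced and the analysis is calibrated", {
  sq <- latin_square_layout(c("A", "B", "placebo"))
  for (i in 1:3) {
    expect_setequal(sq[i, ], c("A", "B", "placebo"))   # once per sequence
    expect_setequal(sq[, i], c("A", "B", "placebo"))   # once per period
  }
  reps <- 4000
  s0 <- simulate_within_patient(trial_scenario(
    "latin_square", trajectory = null_traj,
    treatments = c(active = 0, mid = 0, placebo = 0), n_patients = 18,
    n_reps = reps, seed = 4255), "latin_square")
  expect_true(within_3se(s0$rejection_rate, 0.05, reps))
  conservation_ok(s0)
  expect_error(simulate_within_patient(trial_scenario(
    "latin_square", trajectory = null_traj,
    treatments = c(active = 0, mid = 0, placebo = 0), n_patients = 20),
    "latin_square"), "multiple")
})

test_that("n-of-1 trials analyse the paired measurements of each period pair", {
  s <- simulate_within_patient(trial_scenario(
    "n_of_1", trajectory = null_traj, n_pairs = 3, n_measurements = 2,
    n_reps = 4000, seed = 4256), "n_of_1")
  expect_equal(s$extras$n_differences, 6L)        # 3 pairs x 2 measurements
  expect_equal(s$mean_n_randomized, 1)
  expect_true(within_3se(s$rejection_rate, 0.05, 4000))
  conservation_ok(s)
})

test_that("delayed-start gatekeeping controls the global null and separates
           symptomatic from disease-modifying effects", {
  reps <- 2000
  base <- list(n_per_arm = 60, phase1_weeks = 36, phase2_weeks = 36,
               visit_interval = 12, non_inferiority_margin = 0.08,
               n_reps = reps)
  null_m <- trajectory_model(baseline_mean = 20, baseline_sd = 4,
                             slope_active = 0.25, slope_placebo = 0.25,
                             residual_sd = 3, rho = 0.5)
  s0 <- simulate_delayed_start(do.call(trial_scenario,
    c(list("delayed_start", trajectory = null_m, seed = 4257), base)))
  expect_lte(s0$rejection_rate, 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
  expect_equal(s0$proportion_ever_active, 1)
  conservation_ok(s0)

  # disease-modifying: smaller slope on treatment; all three hypotheses pass
  dm <- trajectory_model(baseline_mean = 20, baseline_sd = 4,
                         slope_active = 0.1, slope_placebo = 0.25,
                         residual_sd = 3, rho = 0.5)
  sdm <- simulate_delayed_start(do.call(trial_scenario,
    c(list("delayed_start", trajectory = dm, seed = 4258), base)))
  expect_gt(sdm$rejection_rate, 0.8)

  # purely symptomatic: strong first-period contrast, but once everyone is
  # treated the groups coincide, so the end-of-study comparison is null
  sym <- trajectory_model(baseline_mean = 20, baseline_sd = 4,
                          slope_active = 0.25, slope_placebo = 0.25,
                          residual_sd = 3, rho = 0.5,
                          symptomatic_offset = -3)
  ssym <- simulate_delayed_start(do.call(trial_scenario,
    c(list("delayed_start", trajectory = sym, seed = 4259), base)))
  expect_gt(ssym$extras$pass_h1, 0.9)
  expect_lte(ssym$extras$end_diff_rejection,
             0.05 + 3 * sqrt(0.05 * 0.95 / reps))

  expect_error(simulate_delayed_start(do.call(trial_scenario,
    c(list("delayed_start", trajectory = dm, seed = 1),
      utils::modifyList(base, list(non_inferiority_margin = -1))))),
    "margin")
})

test_that("placebo-phase trials detect treatment-dependent response latency", {
  reps <- 3000
  s0 <- simulate_placebo_phase(trial_scenario(
    "placebo_phase", latency = latency_model(0.15, 0.15), n_patients = 120,
    delays = c(2, 12), horizon_weeks = 24, n_reps = reps, seed = 4260))
  expect_true(within_3se(s0$rejection_rate, 0.05, reps))
  conservation_ok(s0)
  expect_equal(s0$proportion_ever_active, 1)

  s1 <- simulate_placebo_phase(trial_scenario(
    "placebo_phase", latency = latency_model(0.01, 0.4), n_patients = 40,
    delays = c(2, 12), horizon_weeks = 24, n_reps = 1000, seed = 4261))
  expect_gt(s1$rejection_rate, 0.9)
  # placebo exposure is the assigned delay, capped at the response time
  expect_lte(s1$mean_person_time_on_placebo / 40,
             s1$extras$mean_assigned_delay + 1e-9)

  expect_error(simulate_placebo_phase(trial_scenario(
    "placebo_phase", latency = latency_model(0, 0.4), n_patients = 20,
    delays = c(6, 6), horizon_weeks = 24)), "no contrast")
})

test_that("stepped-wedge rollout treats everyone by the final period and is
           calibrated under cluster heterogeneity", {
  reps <- 4000
  sc0 <- trial_scenario(
    "stepped_wedge", trajectory = trajectory_model(residual_sd = 4),
    n_clusters = 6, n_steps = 5, cluster_size = 8, cluster_sd = 1,
    period_effect_sd = 0.5, n_reps = reps, seed = 4262)
  s0 <- simulate_stepped_wedge(sc0)
  expect_equal(s0$extras$final_period_treated, 1)
  expect_equal(s0$proportion_ever_active, 1)
  expect_true(within_3se(s0$rejection_rate, 0.05, reps))
  conservation_ok(s0)

  # power rises with the cluster-period size
  pow <- vapply(c(2, 8, 32), function(m) {
    simulate_stepped_wedge(trial_scenario(
      "stepped_wedge",
      trajectory = trajectory_model(residual_sd = 4, symptomatic_offset = 2),
      n_clusters = 6, n_steps = 5, cluster_size = m, cluster_sd = 1,
      n_reps = 1000, seed = 4263))$rejection_rate
  }, numeric(1))
  expect_true(all(diff(pow) > 0))

  expect_error(simulate_stepped_wedge(trial_scenario(
    "stepped_wedge", n_clusters = 3, n_steps = 5)), "cluster")
})

test_that("randomised withdrawal randomises the responders and spares placebo time", {
  reps <- 4000
  sc0 <- trial_scenario(
    "randomized_withdrawal",
    binary = binary_model(c(active = 0.6, placebo = 0.2)),
    p_relapse = c(active = 0.3, placebo = 0.3), n_patients = 100,
    run_in_weeks = 8, phase2_relapse_weeks = 16, n_reps = reps, seed = 4264)
  s0 <- simulate_withdrawal(sc0)
  expect_lt(abs(s0$mean_n_randomized - 60), 0.5)   # binomial mean 100 x 0.6
  # exact composite null size (enumerated over responder counts): 0.05135
  expect_true(within_3se(s0$rejection_rate, 0.05135, reps))
  conservation_ok(s0)

  # placebo exposure is far below a parallel trial of the same size/horizon
  parallel_placebo_time <- 50 * 24
  expect_lt(s0$mean_person_time_on_placebo, parallel_placebo_time)

  s1 <- simulate_withdrawal(trial_scenario(
    "randomized_withdrawal",
    binary = binary_model(c(active = 0.6, placebo = 0.2)),
    p_relapse = c(active = 0.15, placebo = 0.55), n_patients = 100,
    run_in_weeks = 8, phase2_relapse_weeks = 16, n_reps = 1000, seed = 4265))
  expect_gt(s1$rejection_rate, 0.9)
})

test_that("early escape truncates exposure at the failure criterion", {
  reps <- 4000
  s0 <- simulate_early_escape(trial_scenario(
    "early_escape", binary = binary_model(c(active = 0.1, placebo = 0.1)),
    n_per_arm = 50, horizon_periods = 4, n_reps = reps, seed = 4266))
  expect_true(within_3se(s0$rejection_rate,
                         oracle_two_prop_size(50, 50, 1 - 0.9^4, 1 - 0.9^4),
                         reps))
  conservation_ok(s0)

  s1 <- simulate_early_escape(trial_scenario(
    "early_escape", binary = binary_model(c(active = 0.1, placebo = 0.5)),
    n_per_arm = 40, horizon_periods = 4, n_reps = 1000, seed = 4267))
  expect_gt(s1$rejection_rate, 0.9)
  expect_lt(s1$mean_person_time_on_placebo, 40 * 4)  # escapes truncate

  s2 <- simulate_early_escape(trial_scenario(
    "early_escape", binary = binary_model(c(active = 0, placebo = 0)),
    n_per_arm = 30, horizon_periods = 4, n_reps = 500, seed = 4268))
  expect_equal(s2$rejection_rate, 0)
  expect_equal(s2$mean_person_time_unexposed, 0)
})

test_that("three-stage trials combine their stage p-values by Fisher's method", {
  reps <- 4000
  s0 <- simulate_three_stage(trial_scenario(
    "three_stage", binary = binary_model(c(active = 0.4, placebo = 0.4)),
    p_relapse = c(active = 0.35, placebo = 0.35), n_per_arm = 150,
    run_in_weeks = 8, phase2_relapse_weeks = 16, n_reps = reps, seed = 4269))
  expect_true(within_3se(s0$rejection_rate, 0.05, reps))
  conservation_ok(s0)

  # moderate effect in every stage: the combination beats each single stage
  s1 <- simulate_three_stage(trial_scenario(
    "three_stage", binary = binary_model(c(active = 0.55, placebo = 0.35)),
    p_relapse = c(active = 0.25, placebo = 0.45), n_per_arm = 60,
    run_in_weeks = 8, phase2_relapse_weeks = 16, n_reps = 2000, seed = 4270))
  expect_gt(s1$rejection_rate,
            max(s1$extras$stage_rejections) - 2 * s1$rejection_se)
  # placebo exposure below a parallel design of the same size and horizon
  expect_lt(s1$mean_person_time_on_placebo, 60 * 24)
})

test_that("a fixed seed reproduces a bit-identical summary", {
  mk <- function() list(
    simulate_parallel(trial_scenario(
      "parallel", binary = binary_model(c(active = 0.6, placebo = 0.4)),
      n_per_arm = 30, n_reps = 300, seed = 4271)),
    simulate_delayed_start(trial_scenario(
      "delayed_start",
      trajectory = trajectory_model(baseline_mean = 20, baseline_sd = 4,
                                    slope_active = 0.1, slope_placebo = 0.25,
                                    residual_sd = 3, rho = 0.5),
      n_per_arm = 20, phase1_weeks = 36, phase2_weeks = 36,
      visit_interval = 12, non_inferiority_margin = 0.1, n_reps = 100,
      seed = 4272)),
    simulate_adaptive("DL", binary_model(c(0.7, 0.3)), n_patients = 30,
                      n_reps = 100, seed = 4273),
    simulate_placebo_phase(trial_scenario(
      "placebo_phase", latency = latency_model(0.05, 0.4), n_patients = 30,
      delays = c(2, 10), horizon_weeks = 20, n_reps = 100, seed = 4274)))
  expect_identical(mk(), mk())
})

test_that("all-patients-treated designs report full active coverage,
           matching their registry flag", {
  reg <- design_registry()
  flagged <- reg$name[reg$all_patients_active_at_end]
  sims <- list(
    delayed_start = simulate_delayed_start(trial_scenario(
      "delayed_start", trajectory = null_traj, n_per_arm = 10,
      phase1_weeks = 12, phase2_weeks = 12, visit_interval = 6,
      non_inferiority_margin = 0.5, n_reps = 50, seed = 4275)),
    placebo_phase = simulate_placebo_phase(trial_scenario(
      "placebo_phase", latency = latency_model(0.05, 0.3), n_patients = 20,
      delays = c(2, 8), horizon_weeks = 16, n_reps = 50, seed = 4276)),
    stepped_wedge = simulate_stepped_wedge(trial_scenario(
      "stepped_wedge", trajectory = trajectory_model(residual_sd = 2),
      n_clusters = 5, n_steps = 5, cluster_size = 4, n_reps = 50,
      seed = 4277)))
  for (nm in flagged) {
    expect_identical(sims[[nm]]$proportion_ever_active, 1,
                     info = nm)
  }
})
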