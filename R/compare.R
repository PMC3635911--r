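#' Compare all feasible designs under a shared scenario
#'
#' Runs the decision algorithm for the supplied context, then simulates
#' every feasible design under a shared scenario template and tabulates
#' operating characteristics side by side: rejection rate with its
#' Monte-Carlo standard error, mean person-time on placebo, proportion of
#' patients ever on active treatment, and mean number randomised. A
#' feasible design for which the template lacks a required model is
#' reported as a "not simulable" row rather than dropped.
#'
#' The template's single disease-treatment description is translated onto
#' each design's parameters: the binary model feeds the parallel arms,
#' urn outcomes, withdrawal/early-escape/three-stage stages; the
#' trajectory model feeds the within-patient and delayed-start designs
#' and the stepped-wedge cluster means; the latency model feeds the
#' placebo-phase design. Each design receives its own seed derived from
#' the template seed and the design's registry position, so per-design
#' results do not depend on the order in which rows are computed.
#'
#' @param ctx A \code{\link{decision_context}}.
#' @param template A list (or \code{trial_scenario}) of shared fields:
#'   models (\code{binary}, \code{trajectory}, \code{latency}), sizes and
#'   durations; design-specific fields are filled with the template values
#'   when present and with translation defaults otherwise.
#' @param seed Integer master seed.
#' @param n_reps Replicates per design.
#' @param alpha Test size.
#' @return An object of class \code{design_comparison}: a data frame with
#'   one row per feasible design (registry order) plus attributes
#'   \code{fingerprint}, \code{caveats} and \code{selection}.
#' @export
compare_designs <- function(ctx, template = list(), seed = 1,
                            n_reps = 1000, alpha = 0.05) {
  sel <- select_designs(ctx)
  rows <- lapply(seq_along(sel$feasible), function(i) {
    nm <- sel$feasible[i]
    pos <- match(nm, design_names())
    sc <- try(.translate_scenario(nm, template,
                                  seed = seed + 1000L * pos,
                                  n_reps = n_reps, alpha = alpha),
              silent = TRUE)
    if (inherits(sc, "try-error"))
      return(data.frame(design = nm, simulable = FALSE,
                        rejection_rate = NA_real_, rejection_se = NA_real_,
                        mean_person_time_on_placebo = NA_real_,
                        proportion_ever_active = NA_real_,
                        mean_n_randomized = NA_real_,
                        stringsAsFactors = FALSE))
    s <- simulate_design(sc)
    data.frame(design = nm, simulable = TRUE,
               rejection_rate = s$rejection_rate,
               rejection_se = s$rejection_se,
               mean_person_time_on_placebo = s$mean_person_time_on_placebo,
               proportion_ever_active = s$proportion_ever_active,
               mean_n_randomized = s$mean_n_randomized,
               stringsAsFactors = FALSE)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(design = character(0), simulable = logical(0),
               rejection_rate = numeric(0), rejection_se = numeric(0),
               mean_person_time_on_placebo = numeric(0),
               proportion_ever_active = numeric(0),
               mean_n_randomized = numeric(0))
  attr(tab, "fingerprint") <- scenario_fingerprint(template, seed, n_reps,
                                                   alpha, ctx)
  attr(tab, "caveats") <- sel$caveats
  attr(tab, "selection") <- sel
  class(tab) <- c("design_comparison", "data.frame")
  tab
}

#' @export
print.design_comparison <- function(x, ...) {
  cat("Design comparison (fingerprint ", attr(x, "fingerprint"), ")\n",
      sep = "")
  if (!nrow(x)) {
    cat("  no feasible designs\n")
  } else {
    print.data.frame(x, row.names = FALSE, digits = 4)
  }
  for (cv in attr(x, "caveats")) cat("Note:", cv, "\n")
  invisible(x)
}

#' Deterministic fingerprint of a comparison configuration
#'
#' FNV-1a hash over the deparsed configuration, so that identical
#' (template, seed, reps, alpha, context) combinations produce identical
#' fingerprints and reproducible tables.
#'
#' @param ... Configuration objects.
#' @return An 8-character hexadecimal string.
#' @export
scenario_fingerprint <- function(...) {
  txt <- paste(deparse(list(...)), collapse = "")
  bytes <- utf8ToInt(txt)
  h <- 0
  # 31-based polynomial rolling hash over a Mersenne-prime modulus; stays
  # in exact double-precision integer range
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# map a shared disease-treatment template onto one design's scenario
.translate_scenario <- function(design, template, seed, n_reps, alpha) {
  tp <- unclass(template)
  g <- function(nm, default = NULL) tp[[nm]] %||% default
  need <- function(x, what) {
    if (is.null(x)) stop("template lacks ", what, call. = FALSE)
    x
  }
  base <- list(seed = seed, n_reps = n_reps, alpha = alpha,
               period_weeks = g("period_weeks", 4))
  extra <- switch(design,
    parallel = list(binary = need(g("binary"), "a binary model"),
                    n_per_arm = g("n_per_arm", 25)),
    factorial = list(n_per_cell = g("n_per_cell",
                                    max(2, (g("n_per_arm", 25) * 2) %/% 4)),
                     effect_a = g("effect_a",
                                  .binary_effect_as_normal(tp)$effect),
                     effect_b = g("effect_b", 0),
                     interaction = g("interaction", 0),
                     sd = g("sd", .binary_effect_as_normal(tp)$sd)),
    crossover = list(trajectory = need(g("trajectory"), "a trajectory model"),
                     n_patients = g("n_patients", g("n_per_arm", 25) * 2)),
    latin_square = {
      tr <- need(g("trajectory"), "a trajectory model")
      list(trajectory = tr,
           treatments = g("treatments",
                          c(active = tr$symptomatic_offset, placebo = 0)),
           n_patients = {
             n0 <- g("n_patients", g("n_per_arm", 25) * 2)
             k <- length(g("treatments",
                           c(active = 1, placebo = 0)))
             n0 - n0 %% k
           })
    },
    n_of_1 = list(trajectory = need(g("trajectory"), "a trajectory model"),
                  n_pairs = g("n_pairs", 3),
                  n_measurements = g("n_measurements", 2)),
    delayed_start = list(trajectory = need(g("trajectory"),
                                           "a trajectory model"),
                         n_per_arm = g("n_per_arm", 25),
                         phase1_weeks = g("phase1_weeks", 24),
                         phase2_weeks = g("phase2_weeks", 24),
                         visit_interval = g("visit_interval", 12),
                         non_inferiority_margin =
                           g("non_inferiority_margin", 0.5)),
    placebo_phase = list(latency = need(g("latency"), "a latency model"),
                         n_patients = g("n_patients",
                                        g("n_per_arm", 25) * 2),
                         delays = g("delays", c(2, 12)),
                         horizon_weeks = g("horizon_weeks", 24)),
    stepped_wedge = list(trajectory = need(g("trajectory"),
                                           "a trajectory model"),
                         n_clusters = g("n_clusters", 6),
                         n_steps = g("n_steps", 5),
                         cluster_size = g("cluster_size", 8),
                         cluster_sd = g("cluster_sd", 0.5),
                         period_effect_sd = g("period_effect_sd", 0)),
    randomized_withdrawal = list(binary = need(g("binary"),
                                               "a binary model"),
                                 p_relapse = g("p_relapse",
                                               .relapse_from_binary(tp)),
                                 n_patients = g("n_patients",
                                                g("n_per_arm", 25) * 2),
                                 run_in_weeks = g("run_in_weeks", 8),
                                 phase2_relapse_weeks =
                                   g("phase2_relapse_weeks", 16)),
    early_escape = list(binary = .failure_from_binary(tp),
                        n_per_arm = g("n_per_arm", 25),
                        horizon_periods = g("horizon_periods", 4)),
    three_stage = list(binary = need(g("binary"), "a binary model"),
                       p_relapse = g("p_relapse", .relapse_from_binary(tp)),
                       n_per_arm = g("n_per_arm", 25),
                       run_in_weeks = g("run_in_weeks", 8),
                       phase2_relapse_weeks = g("phase2_relapse_weeks", 16)),
    adaptive_randomization = list(binary = need(g("binary"),
                                                "a binary model"),
                                  n_patients = g("n_patients",
                                                 g("n_per_arm", 25) * 2),
                                  rule = g("rule", "PW")))
  do.call(trial_scenario, c(list(design = design), base, extra))
}

# translate a binary success-probability contrast into a normal effect of
# matched power (probit-scale difference with unit sd), for designs that
# need a continuous endpoint when only a binary model is supplied
.binary_effect_as_normal <- function(tp) {
  bm <- tp$binary
  if (is.null(bm)) return(list(effect = 0.5, sd = 1))
  p <- bm$p_success
  list(effect = stats::qnorm(p[1]) - stats::qnorm(p[2]), sd = 1)
}

# relapse probabilities implied by the shared binary model: staying well on
# active ~ responding; relapse on placebo ~ 1 - placebo response
.relapse_from_binary <- function(tp) {
  bm <- tp$binary
  if (is.null(bm)) stop("template lacks relapse probabilities", call. = FALSE)
  p <- bm$p_success
  c(active = unname(1 - p["active"]), placebo = unname(1 - p["placebo"]))
}

# per-period failure probabilities implied by the shared binary model
.failure_from_binary <- function(tp) {
  bm <- tp$binary
  if (is.null(bm)) stop("template lacks a binary model", call. = FALSE)
  p <- 1 - bm$p_success
  if (!is.null(names(p)) && "placebo" %in% names(p)) {
    act <- setdiff(names(p), "placebo")[1]
    binary_model(c(p[act], p["placebo"])[c(act, "placebo")])
  } else binary_model(p)
}
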