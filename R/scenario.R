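#' Trial scenario for a design simulator
#'
#' Bundles the response model(s) and design parameters for one simulation.
#' Only the fields a given design uses are required; each simulator checks
#' its own preconditions. Unknown fields are rejected to catch typos.
#'
#' @param design A design identifier (see \code{\link{design_names}}).
#' @param ... Scenario fields. Common ones: \code{binary} (a
#'   \code{\link{binary_model}}), \code{trajectory} (a
#'   \code{\link{trajectory_model}}), \code{latency} (a
#'   \code{\link{latency_model}}), \code{n_per_arm}, \code{n_patients},
#'   \code{alpha}, \code{seed}, \code{n_reps}, \code{period_weeks},
#'   \code{n_periods}, \code{ratio}, \code{run_in_weeks},
#'   \code{responder_threshold}, \code{horizon_periods}, \code{delays},
#'   \code{delay_probs}, \code{horizon_weeks}, \code{n_clusters},
#'   \code{n_steps}, \code{cluster_size}, \code{cluster_sd},
#'   \code{period_effect_sd}, \code{phase1_weeks}, \code{phase2_weeks},
#'   \code{visit_interval}, \code{non_inferiority_margin},
#'   \code{n_pairs}, \code{n_measurements}, \code{washout},
#'   \code{effect_a}, \code{effect_b}, \code{interaction}, \code{sd},
#'   \code{n_per_cell}, \code{treatments}.
#' @return An object of class \code{trial_scenario}.
#' @export
trial_scenario <- function(design, ...) {
  if (!design %in% design_names())
    stop("unknown design ", dQuote(design), "; valid identifiers are: ",
         paste(design_names(), collapse = ", "), call. = FALSE)
  fields <- list(...)
  allowed <- c("binary", "trajectory", "latency", "n_per_arm", "n_patients",
               "alpha", "seed", "n_reps", "period_weeks", "n_periods",
               "ratio", "run_in_weeks", "responder_threshold",
               "horizon_periods", "delays", "delay_probs", "horizon_weeks",
               "n_clusters", "n_steps", "cluster_size", "cluster_sd",
               "period_effect_sd", "phase1_weeks", "phase2_weeks",
               "visit_interval", "non_inferiority_margin", "n_pairs",
               "n_measurements", "washout", "effect_a", "effect_b",
               "interaction", "sd", "n_per_cell", "treatments",
               "p_relapse", "phase2_relapse_weeks", "rule", "initial_urn")
  bad <- setdiff(names(fields), allowed)
  if (length(bad))
    stop("unknown scenario field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  defaults <- list(alpha = 0.05, seed = 1, n_reps = 1000, period_weeks = 1)
  for (nm in names(defaults))
    if (is.null(fields[[nm]])) fields[[nm]] <- defaults[[nm]]
  if (fields$alpha <= 0 || fields$alpha >= 1)
    stop("alpha must be in (0, 1)", call. = FALSE)
  structure(c(list(design = design), fields), class = "trial_scenario")
}

#' Operating-characteristic summary of one simulated design
#'
#' Constructed by the design simulators; not usually called directly.
#'
#' @param design Design identifier.
#' @param n_reps Number of replicates simulated.
#' @param alpha Test size.
#' @param rejection_rate Proportion of informative replicates whose primary
#'   test rejected.
#' @param n_informative Number of informative replicates.
#' @param person_time Named numeric: mean person-time (weeks) on
#'   \code{placebo}, on \code{active} treatment, and \code{unexposed}.
#' @param total_follow_up Total follow-up person-time (weeks) per
#'   replicate; equals the sum of the three person-time components.
#' @param proportion_ever_active Proportion of randomised patients ever on
#'   active treatment.
#' @param mean_n_randomized Mean number of randomised patients.
#' @param allocation Named mean allocation proportions per arm.
#' @param extras Design-specific list (replicate-level statistics etc.).
#' @return An object of class \code{simulation_summary}.
#' @export
simulation_summary <- function(design, n_reps, alpha, rejection_rate,
                               n_informative = n_reps, person_time,
                               total_follow_up, proportion_ever_active,
                               mean_n_randomized, allocation = NULL,
                               extras = list()) {
  r <- rejection_rate
  stopifnot(is.na(r) || (r >= 0 && r <= 1),
            proportion_ever_active >= 0, proportion_ever_active <= 1)
  se <- if (is.na(r) || n_informative == 0) NA_real_
        else sqrt(r * (1 - r) / n_informative)
  structure(list(
    design = design, n_reps = n_reps, alpha = alpha,
    rejection_rate = r, rejection_se = se, n_informative = n_informative,
    mean_person_time_on_placebo = unname(person_time["placebo"]),
    mean_person_time_on_active = unname(person_time["active"]),
    mean_person_time_unexposed = unname(person_time["unexposed"]),
    total_follow_up = total_follow_up,
    proportion_ever_active = proportion_ever_active,
    mean_n_randomized = mean_n_randomized,
    allocation = allocation,
    extras = extras
  ), class = "simulation_summary")
}

#' @export
print.simulation_summary <- function(x, ...) {
  cat("Simulation summary:", x$design, "\n")
  cat(sprintf("  replicates: %d (informative: %d)\n",
              x$n_reps, x$n_informative))
  cat(sprintf("  rejection rate: %.4f (MC s.e. %.4f) at alpha = %g\n",
              x$rejection_rate, x$rejection_se, x$alpha))
  cat(sprintf("  mean person-time: placebo %.2f, active %.2f, unexposed %.2f (weeks)\n",
              x$mean_person_time_on_placebo, x$mean_person_time_on_active,
              x$mean_person_time_unexposed))
  cat(sprintf("  proportion ever on active treatment: %.3f\n",
              x$proportion_ever_active))
  cat(sprintf("  mean number randomised: %.1f\n", x$mean_n_randomized))
  if (!is.null(x$allocation))
    cat("  mean allocation:",
        paste(sprintf("%s %.3f", names(x$allocation), x$allocation),
              collapse = ", "), "\n")
  invisible(x)
}

# ---- vectorised test helpers (internal) -------------------------------------

# pooled two-proportion z-test (score test), two-sided; vectorised over
# replicates. Returns p-values and rejection indicators.
two_prop_z <- function(x1, n1, x2, n2, alpha = 0.05) {
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- ifelse(se > 0, (p1 - p2) / se, 0)
  p <- 2 * stats::pnorm(-abs(z))
  list(z = z, p = p, reject = abs(z) > stats::qnorm(1 - alpha / 2))
}

# Welch two-sample t-test from summary statistics; vectorised.
welch_t <- function(m1, s1, n1, m2, s2, n2, alpha = 0.05) {
  v1 <- s1^2 / n1; v2 <- s2^2 / n2
  se <- sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  t <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p, reject = p < alpha)
}

# one-sample / paired t-test from summary statistics; vectorised.
paired_t <- function(mean_d, sd_d, n, alpha = 0.05) {
  t <- mean_d / (sd_d / sqrt(n))
  p <- 2 * stats::pt(-abs(t), n - 1)
  list(t = t, p = p, reject = p < alpha)
}

# row means / sds of a matrix, fast
.row_mean <- function(m) rowMeans(m)
.row_sd <- function(m) {
  n <- ncol(m)
  sqrt((rowSums(m^2) - n * rowMeans(m)^2) / (n - 1))
}
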