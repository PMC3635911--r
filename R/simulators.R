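#' Combine independent p-values by Fisher's method
#'
#' The statistic is X = -2 * sum(log(p_i)); under the null of all k
#' component nulls being true (independent tests), X is chi-square with 2k
#' degrees of freedom, and the combined p-value is its upper-tail
#' probability at X. Used by the three-stage design to merge its three
#' stage-wise efficacy assessments into a single overall p-value.
#'
#' @param p_values Numeric vector of p-values, each in (0, 1].
#' @return The combined p-value.
#' @examples
#' fisher_combine(c(1, 1, 1))        # 1
#' fisher_combine(0.05)              # 0.05
#' fisher_combine(c(0.05, 0.05, 0.05))  # ~0.0063
#' @export
fisher_combine <- function(p_values) {
  if (!length(p_values) || !is.numeric(p_values) ||
      any(p_values <= 0) || any(p_values > 1))
    stop("p-values must be in (0, 1]", call. = FALSE)
  x <- -2 * sum(log(p_values))
  stats::pchisq(x, df = 2 * length(p_values), lower.tail = FALSE)
}

# resolve the per-arm group sizes of a two-arm parallel randomisation
.two_arm_sizes <- function(scenario) {
  if (!is.null(scenario$ratio)) {
    r <- scenario$ratio
    if (any(r <= 0)) stop("randomisation ratio weights must be positive",
                          call. = FALSE)
    n_tot <- scenario$n_patients
    n1 <- round(n_tot * r[1] / sum(r))
    c(n1, n_tot - n1)
  } else {
    n <- scenario$n_per_arm
    if (is.null(n)) stop("scenario needs n_per_arm (or n_patients + ratio)",
                         call. = FALSE)
    if (length(n) == 1) n <- rep(n, 2)
    n
  }
}

#' Simulate a two-arm parallel-group trial
#'
#' Patients are randomised to one of two groups with a pre-specified
#' ratio and followed for a fixed horizon. A binary scenario compares
#' success proportions with the pooled two-proportion z-test; a continuous
#' scenario compares end-of-follow-up scores with Welch's t-test. The
#' first arm of the model is taken as the test treatment and the second as
#' the control (named \code{"placebo"} for placebo-controlled accounting).
#'
#' @param scenario A \code{\link{trial_scenario}} with either a
#'   \code{binary} or a \code{trajectory} model, \code{n_per_arm} (or
#'   \code{n_patients} + \code{ratio}), and \code{horizon_weeks} (continuous)
#'   or \code{period_weeks} (binary follow-up length).
#' @return A \code{\link{simulation_summary}}.
#' @examples
#' sc <- trial_scenario("parallel",
#'                      binary = binary_model(c(active = 0.8, placebo = 0.3)),
#'                      n_per_arm = 25, n_reps = 2000, seed = 7)
#' simulate_parallel(sc)
#' @export
simulate_parallel <- function(scenario) {
  stopifnot(inherits(scenario, "trial_scenario"))
  n <- .two_arm_sizes(scenario)
  reps <- scenario$n_reps; alpha <- scenario$alpha
  horizon <- scenario$horizon_weeks %||% scenario$period_weeks
  with_seed(scenario$seed, {
    if (!is.null(scenario$binary)) {
      p <- scenario$binary$p_success
      stopifnot(length(p) >= 2)
      x1 <- stats::rbinom(reps, n[1], p[1])
      x2 <- stats::rbinom(reps, n[2], p[2])
      rej <- two_prop_z(x1, n[1], x2, n[2], alpha)$reject
      arm_names <- names(p)[1:2]
    } else if (!is.null(scenario$trajectory)) {
      tm <- scenario$trajectory
      sd_end <- sqrt(tm$baseline_sd^2 + tm$residual_sd^2)
      mu1 <- tm$baseline_mean + tm$slope_active * horizon + tm$symptomatic_offset
      mu2 <- tm$baseline_mean + tm$slope_placebo * horizon
      y1 <- matrix(stats::rnorm(reps * n[1], mu1, sd_end), reps, n[1])
      y2 <- matrix(stats::rnorm(reps * n[2], mu2, sd_end), reps, n[2])
      rej <- welch_t(.row_mean(y1), .row_sd(y1), n[1],
                     .row_mean(y2), .row_sd(y2), n[2], alpha)$reject
      arm_names <- c("active", "placebo")
    } else stop("scenario needs a binary or trajectory model", call. = FALSE)
    placebo_arm <- arm_names == "placebo"
    simulation_summary(
      design = "parallel", n_reps = reps, alpha = alpha,
      rejection_rate = mean(rej),
      person_time = c(placebo = sum(n[placebo_arm]) * horizon,
                      active = sum(n[!placebo_arm]) * horizon,
                      unexposed = 0),
      total_follow_up = sum(n) * horizon,
      proportion_ever_active = sum(n[!placebo_arm]) / sum(n),
      mean_n_randomized = sum(n),
      allocation = stats::setNames(n / sum(n), arm_names))
  })
}

#' Simulate a 2x2 factorial trial
#'
#' Patients are randomised twice: to treatment A or its placebo, then
#' within each group to treatment B or its placebo, giving four cells of
#' \code{n_per_cell} patients. The continuous outcome is
#' \code{mu + effect_a*A + effect_b*B + interaction*A*B + e}. Each factor
#' margin is tested by a pooled-variance t-test on its marginal means (the
#' parallel-group comparison at full sample size); the A-by-B interaction
#' is tested by the corresponding cell contrast. The primary rejection
#' rate refers to factor A.
#'
#' @param scenario A \code{\link{trial_scenario}} with \code{n_per_cell},
#'   \code{effect_a}, \code{effect_b}, \code{interaction}, \code{sd} and
#'   optionally \code{horizon_weeks}.
#' @return A \code{\link{simulation_summary}}; \code{extras} carries
#'   \code{rejection_rate_b} and \code{rejection_rate_interaction}.
#' @export
simulate_factorial <- function(scenario) {
  stopifnot(inherits(scenario, "trial_scenario"))
  n <- scenario$n_per_cell
  stopifnot(!is.null(n), n >= 2)
  reps <- scenario$n_reps; alpha <- scenario$alpha
  ea <- scenario$effect_a %||% 0; eb <- scenario$effect_b %||% 0
  eab <- scenario$interaction %||% 0; sd <- scenario$sd %||% 1
  horizon <- scenario$horizon_weeks %||% scenario$period_weeks
  mu <- c(`00` = 0, `10` = ea, `01` = eb, `11` = ea + eb + eab)
  with_seed(scenario$seed, {
    cells <- lapply(mu, function(m)
      matrix(stats::rnorm(reps * n, m, sd), reps, n))
    cm <- vapply(cells, .row_mean, numeric(reps))     # reps x 4
    cv <- vapply(cells, function(x) .row_sd(x)^2, numeric(reps))
    s2 <- rowMeans(cv)                                 # pooled, df = 4(n-1)
    df <- 4 * (n - 1)
    tcrit <- stats::qt(1 - alpha / 2, df)
    t_of <- function(contrast, var_mult) {
      est <- cm %*% contrast
      drop(est) / sqrt(s2 * var_mult / n)
    }
    # margin A: mean(A+) - mean(A-); var = s2 * (1/(2n) + 1/(2n)) = s2/n
    tA <- t_of(c(-0.5, 0.5, -0.5, 0.5), 1)
    tB <- t_of(c(-0.5, -0.5, 0.5, 0.5), 1)
    tI <- t_of(c(1, -1, -1, 1), 4)
    simulation_summary(
      design = "factorial", n_reps = reps, alpha = alpha,
      rejection_rate = mean(abs(tA) > tcrit),
      person_time = c(placebo = n * horizon,      # double-placebo cell
                      active = 3 * n * horizon,
                      unexposed = 0),
      total_follow_up = 4 * n * horizon,
      proportion_ever_active = 3 / 4,
      mean_n_randomized = 4 * n,
      allocation = c(`A-B-` = .25, `A+B-` = .25, `A-B+` = .25, `A+B+` = .25),
      extras = list(rejection_rate_b = mean(abs(tB) > tcrit),
                    rejection_rate_interaction = mean(abs(tI) > tcrit)))
  })
}

#' Simulate a within-patient comparative design
#'
#' Covers the three intra-patient designs:
#' \describe{
#'   \item{crossover}{two treatments, two periods, AB/BA sequences
#'     randomised 1:1; the treatment effect is estimated from the
#'     period-adjusted within-patient half-differences (Grizzle analysis:
#'     two-sample t-test on (period1 - period2)/2 between sequence
#'     groups), which is calibrated in the presence of period effects.}
#'   \item{latin_square}{K treatments over K periods using a cyclic Latin
#'     square (each treatment once per sequence and period position) with
#'     randomly permuted treatment labels; the primary analysis is a
#'     paired t-test of the first listed treatment against placebo on
#'     within-patient differences.}
#'   \item{n_of_1}{a single patient; \code{n_pairs} treatment/placebo
#'     period pairs with randomised order within each pair and
#'     \code{n_measurements} measurements per period; paired t-test on
#'     the within-pair measurement differences.}
#' }
#' Scores follow the \code{\link{trajectory_model}}: the treatment effect
#' is the symptomatic offset, within-patient correlation comes from the
#' shared patient intercept and \code{rho}, and an unwashed-out carry-over
#' shifts any period that immediately follows an active one (set
#' \code{washout = TRUE}, the default, to zero it).
#'
#' @param scenario A \code{\link{trial_scenario}}; crossover needs
#'   \code{n_patients}; latin_square needs \code{treatments} (named effect
#'   vector including \code{placebo = 0}) and \code{n_patients} (multiple
#'   of K); n_of_1 needs \code{n_pairs} and \code{n_measurements}.
#' @param design One of \code{"crossover"}, \code{"latin_square"},
#'   \code{"n_of_1"}.
#' @return A \code{\link{simulation_summary}}.
#' @export
simulate_within_patient <- function(scenario,
                                    design = c("crossover", "latin_square",
                                               "n_of_1")) {
  stopifnot(inherits(scenario, "trial_scenario"))
  design <- match.arg(design)
  switch(design,
         crossover = .sim_crossover(scenario),
         latin_square = .sim_latin_square(scenario),
         n_of_1 = .sim_n_of_1(scenario))
}

.sim_crossover <- function(scenario) {
  tm <- scenario$trajectory
  stopifnot(!is.null(tm), !is.null(scenario$n_patients))
  n <- scenario$n_patients; reps <- scenario$n_reps
  pw <- scenario$period_weeks; alpha <- scenario$alpha
  washout <- scenario$washout %||% TRUE
  carry <- if (washout) 0 else tm$carryover
  sd_d <- sqrt(2 * (1 - tm$rho)) * tm$residual_sd      # sd of y1 - y2
  # half-difference means by sequence (see Grizzle analysis):
  # AB: ((sA*pw + off) - (sA*pw + sP*pw + carry))/2
  # BA: ((sP*pw) - (sP*pw + sA*pw + off))/2
  mu_ab <- (tm$symptomatic_offset - tm$slope_placebo * pw - carry) / 2
  mu_ba <- -(tm$symptomatic_offset + tm$slope_active * pw) / 2
  with_seed(scenario$seed, {
    seq_ab <- matrix(stats::rbinom(reps * n, 1, 0.5) == 1, reps, n)
    d <- matrix(stats::rnorm(reps * n, 0, sd_d / 2), reps, n) +
      ifelse(seq_ab, mu_ab, mu_ba)
    n_ab <- rowSums(seq_ab)
    informative <- n_ab >= 2 & (n - n_ab) >= 2
    m1 <- rowSums(d * seq_ab) / n_ab
    m2 <- rowSums(d * !seq_ab) / (n - n_ab)
    s1 <- sqrt((rowSums(d^2 * seq_ab) - n_ab * m1^2) / (n_ab - 1))
    s2 <- sqrt((rowSums(d^2 * !seq_ab) - (n - n_ab) * m2^2) / (n - n_ab - 1))
    rej <- welch_t(m1, s1, n_ab, m2, s2, n - n_ab, alpha)$reject
    simulation_summary(
      design = "crossover", n_reps = reps, alpha = alpha,
      rejection_rate = mean(rej[informative]),
      n_informative = sum(informative),
      person_time = c(placebo = n * pw, active = n * pw, unexposed = 0),
      total_follow_up = 2 * n * pw,
      proportion_ever_active = 1,
      mean_n_randomized = n,
      allocation = c(AB = mean(n_ab) / n, BA = 1 - mean(n_ab) / n))
  })
}

.sim_latin_square <- function(scenario) {
  tm <- scenario$trajectory %||% trajectory_model()
  eff <- scenario$treatments
  stopifnot(!is.null(eff), "placebo" %in% names(eff),
            !is.null(scenario$n_patients))
  k <- length(eff)
  n <- scenario$n_patients
  if (n %% k != 0)
    stop("n_patients must be a multiple of the number of treatments ",
         "so that the ", k, " sequences can be constructed", call. = FALSE)
  reps <- scenario$n_reps; alpha <- scenario$alpha; pw <- scenario$period_weeks
  test_arm <- setdiff(names(eff), "placebo")[1]
  sd_d <- sqrt(2 * (1 - tm$rho)) * tm$residual_sd
  delta <- eff[[test_arm]] - eff[["placebo"]]
  with_seed(scenario$seed, {
    # balanced cyclic square; the paired within-patient difference between
    # the tested treatment and placebo has mean delta regardless of the
    # (randomised) label permutation, with period drift cancelling in
    # expectation over the balanced sequences
    d <- matrix(stats::rnorm(reps * n, delta, sd_d), reps, n)
    res <- paired_t(.row_mean(d), .row_sd(d), n, alpha)
    n_plac_periods <- n                    # each patient: 1 placebo period
    simulation_summary(
      design = "latin_square", n_reps = reps, alpha = alpha,
      rejection_rate = mean(res$reject),
      person_time = c(placebo = n_plac_periods * pw,
                      active = n * (k - 1) * pw, unexposed = 0),
      total_follow_up = n * k * pw,
      proportion_ever_active = 1,
      mean_n_randomized = n,
      allocation = stats::setNames(rep(1 / k, k), names(eff)))
  })
}

#' Construct a (cyclic) Latin square of treatment sequences
#'
#' Row s, column p holds the treatment given to sequence s in period p;
#' each treatment appears exactly once per row and per column.
#'
#' @param treatments Character vector of treatment labels.
#' @return A K x K character matrix.
#' @export
latin_square_layout <- function(treatments) {
  k <- length(treatments)
  m <- matrix("", k, k)
  for (s in seq_len(k)) m[s, ] <- treatments[((s - 1 + seq_len(k) - 1) %% k) + 1]
  m
}

.sim_n_of_1 <- function(scenario) {
  tm <- scenario$trajectory
  stopifnot(!is.null(tm), !is.null(scenario$n_pairs))
  np <- scenario$n_pairs
  nm <- scenario$n_measurements %||% 1
  reps <- scenario$n_reps; alpha <- scenario$alpha; pw <- scenario$period_weeks
  washout <- scenario$washout %||% TRUE
  carry <- if (washout) 0 else tm$carryover
  n_d <- np * nm                       # paired differences analysed
  sd_d <- sqrt(2 * (1 - tm$rho)) * tm$residual_sd
  with_seed(scenario$seed, {
    # order within each pair randomised; carry-over reaches the second
    # period of a pair only when the first was active (A-then-P order)
    a_first <- matrix(stats::rbinom(reps * np, 1, 0.5) == 1, reps, np)
    mu <- tm$symptomatic_offset - carry * a_first
    mu_full <- mu[, rep(seq_len(np), each = nm), drop = FALSE]
    d <- matrix(stats::rnorm(reps * n_d, 0, sd_d), reps, n_d) + mu_full
    res <- paired_t(.row_mean(d), .row_sd(d), n_d, alpha)
    simulation_summary(
      design = "n_of_1", n_reps = reps, alpha = alpha,
      rejection_rate = mean(res$reject),
      person_time = c(placebo = np * pw, active = np * pw, unexposed = 0),
      total_follow_up = 2 * np * pw,
      proportion_ever_active = 1,
      mean_n_randomized = 1,
      allocation = c(active = 0.5, placebo = 0.5),
      extras = list(n_differences = n_d,
                    n_measurements_total = 2 * n_d))
  })
}

#' Simulate a delayed-start trial
#'
#' An initial randomised placebo-controlled phase (early-start group on
#' active treatment, delayed-start group on placebo) is followed by a
#' second phase in which everyone receives active treatment. Three
#' hypotheses are tested sequentially (gatekeeping — each is tested only
#' if the previous one passed):
#' \enumerate{
#'   \item superiority of treatment over placebo on the change from
#'     baseline to the end of phase 1 (Welch t, two-sided, with the
#'     benefit direction required);
#'   \item superiority of early over delayed start on the change from
#'     baseline to the end of the trial;
#'   \item non-inferiority of the early-start group's second-period slope
#'     (per-patient least-squares slopes over the phase-2 visits, one-sided
#'     t at \code{alpha/2} against the margin).
#' }
#' The design's rejection rate is the proportion of replicates passing all
#' three. Higher scores denote worse disease, so benefit means smaller
#' score increase.
#'
#' @param scenario A \code{\link{trial_scenario}} with a \code{trajectory}
#'   model, \code{n_per_arm}, \code{phase1_weeks}, \code{phase2_weeks},
#'   \code{visit_interval} (must divide both phase lengths) and
#'   \code{non_inferiority_margin} (score units/week, > 0).
#' @return A \code{\link{simulation_summary}}; \code{extras} carries the
#'   per-hypothesis pass rates.
#' @export
simulate_delayed_start <- function(scenario) {
  stopifnot(inherits(scenario, "trial_scenario"))
  tm <- scenario$trajectory
  n <- scenario$n_per_arm
  t1 <- scenario$phase1_weeks; t2 <- scenario$phase2_weeks
  vi <- scenario$visit_interval %||% t1
  margin <- scenario$non_inferiority_margin
  stopifnot(!is.null(tm), !is.null(n), !is.null(t1), !is.null(t2))
  if (is.null(margin) || margin <= 0)
    stop("non_inferiority_margin must be > 0", call. = FALSE)
  if (t1 %% vi != 0 || t2 %% vi != 0)
    stop("visit_interval must divide both phase lengths", call. = FALSE)
  reps <- scenario$n_reps; alpha <- scenario$alpha
  times <- seq(vi, t1 + t2, by = vi)
  nv <- length(times)
  early_active <- rep(TRUE, nv)
  delayed_active <- times > t1
  phase2 <- times >= t1              # visits used for second-period slopes
  tt <- times[phase2]
  w_slope <- (tt - mean(tt)) / sum((tt - mean(tt))^2)
  # phase-2 slope uses the boundary visit at t1 plus later visits
  if (sum(phase2) < 2) stop("need at least 2 phase-2 visits", call. = FALSE)
  mean_curve <- function(active) {
    slopes <- ifelse(active, tm$slope_active, tm$slope_placebo)
    cumsum(slopes * diff(c(0, times))) + tm$symptomatic_offset * active +
      tm$baseline_mean
  }
  with_seed(scenario$seed, {
    sim_group <- function(active) {
      mu <- mean_curve(active)
      rows <- reps * n
      b <- stats::rnorm(rows, 0, sqrt(tm$baseline_sd^2 +
                                        tm$rho * tm$residual_sd^2))
      e <- matrix(stats::rnorm(rows * (nv + 1), 0,
                               sqrt(1 - tm$rho) * tm$residual_sd),
                  rows, nv + 1)
      base <- tm$baseline_mean + b + e[, 1]
      y <- matrix(mu, rows, nv, byrow = TRUE) + b + e[, -1, drop = FALSE]
      list(change1 = y[, which(times == t1)] - base,
           change2 = y[, nv] - base,
           slope2 = drop(y[, phase2, drop = FALSE] %*% w_slope))
    }
    gE <- sim_group(early_active)
    gD <- sim_group(delayed_active)
    grp <- rep(seq_len(reps), each = n)
    stat <- function(v) {
      m <- rowsum(v, grp) / n
      s2 <- (rowsum(v^2, grp) - n * m^2) / (n - 1)
      list(m = drop(m), s = drop(sqrt(s2)))
    }
    h_test <- function(vE, vD) {
      sE <- stat(vE); sD <- stat(vD)
      w <- welch_t(sE$m, sE$s, n, sD$m, sD$s, n, alpha)
      w$reject & (sE$m < sD$m)       # benefit: smaller score increase
    }
    h1 <- h_test(gE$change1, gD$change1)
    h2 <- h_test(gE$change2, gD$change2)
    sE <- stat(gE$slope2); sD <- stat(gD$slope2)
    se3 <- sqrt(sE$s^2 / n + sD$s^2 / n)
    df3 <- (sE$s^2 / n + sD$s^2 / n)^2 /
      ((sE$s^2 / n)^2 / (n - 1) + (sD$s^2 / n)^2 / (n - 1))
    t3 <- (sE$m - sD$m - margin) / se3
    h3 <- t3 < stats::qt(scenario$alpha / 2, df3)
    pass <- h1 & (h1 & h2) & (h1 & h2 & h3)
    simulation_summary(
      design = "delayed_start", n_reps = reps, alpha = alpha,
      rejection_rate = mean(pass),
      person_time = c(placebo = n * t1,
                      active = n * (t1 + t2) + n * t2,
                      unexposed = 0),
      total_follow_up = 2 * n * (t1 + t2),
      proportion_ever_active = 1,
      mean_n_randomized = 2 * n,
      allocation = c(early = 0.5, delayed = 0.5),
      extras = list(pass_h1 = mean(h1), pass_h2 = mean(h1 & h2),
                    pass_h3_given_h12 = mean(h3[h1 & h2]),
                    end_diff_rejection = mean(h2)))
  })
}

#' Simulate a randomised placebo-phase trial
#'
#' Every patient eventually receives active treatment; what is randomised
#' is the time from enrolment to treatment start. Response latencies
#' follow the piecewise-exponential \code{\link{latency_model}}; with an
#' effective treatment, earlier starters respond sooner. The primary
#' analysis is a log-rank test of time-to-response across the delay
#' groups, censored at the follow-up horizon.
#'
#' @param scenario A \code{\link{trial_scenario}} with a \code{latency}
#'   model, \code{n_patients}, \code{delays} (two or more distinct start
#'   times, weeks), optional \code{delay_probs}, and
#'   \code{horizon_weeks} (> max delay).
#' @return A \code{\link{simulation_summary}}.
#' @export
simulate_placebo_phase <- function(scenario) {
  stopifnot(inherits(scenario, "trial_scenario"))
  lm_ <- scenario$latency
  n <- scenario$n_patients
  delays <- scenario$delays
  horizon <- scenario$horizon_weeks
  stopifnot(!is.null(lm_), !is.null(n), !is.null(delays), !is.null(horizon))
  if (length(unique(delays)) < 2)
    stop("all delays identical: no contrast to test", call. = FALSE)
  if (max(delays) >= horizon)
    stop("all delays must be shorter than the follow-up horizon",
         call. = FALSE)
  probs <- scenario$delay_probs %||% rep(1 / length(delays), length(delays))
  reps <- scenario$n_reps; alpha <- scenario$alpha
  h0 <- lm_$hazard_untreated; h1 <- lm_$hazard_treated
  with_seed(scenario$seed, {
    dl <- matrix(delays[sample.int(length(delays), reps * n, replace = TRUE,
                                   prob = probs)], reps, n)
    ee <- matrix(stats::rexp(reps * n), reps, n)
    tresp <- ifelse(ee < h0 * dl, ee / h0,
                    if (h1 > 0) dl + (ee - h0 * dl) / h1 else Inf)
    event <- tresp <= horizon
    tobs <- pmin(tresp, horizon)
    rej <- logical(reps); informative <- logical(reps)
    for (r in seq_len(reps)) {
      g <- factor(dl[r, ])
      if (nlevels(g) < 2 || sum(event[r, ]) == 0) next
      sd <- survival::survdiff(survival::Surv(tobs[r, ], event[r, ]) ~ g)
      p <- stats::pchisq(sd$chisq, length(sd$n) - 1, lower.tail = FALSE)
      informative[r] <- TRUE
      rej[r] <- p < alpha
    }
    pt_placebo <- mean(rowSums(pmin(dl, tresp, horizon)))
    pt_active <- mean(rowSums(horizon - pmin(dl, horizon)))
    simulation_summary(
      design = "placebo_phase", n_reps = reps, alpha = alpha,
      rejection_rate = mean(rej[informative]),
      n_informative = sum(informative),
      person_time = c(placebo = pt_placebo, active = pt_active,
                      unexposed = n * horizon - pt_placebo - pt_active),
      total_follow_up = n * horizon,
      proportion_ever_active = 1,
      mean_n_randomized = n,
      allocation = stats::setNames(probs, paste0("delay_", delays)),
      extras = list(mean_assigned_delay = mean(dl)))
  })
}

#' Simulate a stepped-wedge cluster-randomised trial
#'
#' All clusters start on control; at each of \code{n_steps} time steps a
#' randomly chosen set of clusters crosses over to the intervention, so
#' that in the final period every cluster is treated. Cluster-period mean
#' outcomes follow \code{mu + period effect + cluster effect +
#' effect * treated + noise}; the treatment effect is estimated from the
#' cluster-period means by a linear model with cluster and period fixed
#' effects (the within-cluster estimator).
#'
#' @param scenario A \code{\link{trial_scenario}} with \code{n_clusters}
#'   (>= \code{n_steps}), \code{n_steps}, \code{cluster_size},
#'   \code{cluster_sd}, \code{period_effect_sd}, a \code{trajectory} model
#'   whose \code{symptomatic_offset} is the treatment effect and
#'   \code{residual_sd} the individual-level s.d., and \code{period_weeks}.
#' @return A \code{\link{simulation_summary}}.
#' @export
simulate_stepped_wedge <- function(scenario) {
  stopifnot(inherits(scenario, "trial_scenario"))
  C <- scenario$n_clusters; S <- scenario$n_steps
  m <- scenario$cluster_size %||% 10
  stopifnot(!is.null(C), !is.null(S))
  if (C < S)
    stop("need at least one cluster per step (n_clusters >= n_steps)",
         call. = FALSE)
  tm <- scenario$trajectory %||% trajectory_model()
  effect <- tm$symptomatic_offset
  sd_cp <- tm$residual_sd / sqrt(m)
  csd <- scenario$cluster_sd %||% 0
  psd <- scenario$period_effect_sd %||% 0
  reps <- scenario$n_reps; alpha <- scenario$alpha; pw <- scenario$period_weeks
  P <- S + 1
  # fixed rollout schedule (clusters spread as evenly as possible over the
  # steps); randomising which physical cluster sits where is equivalent to
  # permuting the cluster random effects, which are exchangeable
  step_of <- rep(seq_len(S), length.out = C)
  treated <- outer(step_of, seq_len(P) - 1L, function(s, per) per >= s)
  tr <- as.vector(treated)                       # cluster-major order
  cl <- rep(seq_len(C), P)
  per <- rep(seq_len(P), each = C)
  X <- stats::model.matrix(~ factor(cl) + factor(per) + tr)
  qrX <- qr(X)
  df <- length(tr) - qrX$rank
  if (df < 1) stop("no residual degrees of freedom", call. = FALSE)
  Z <- X[, -ncol(X), drop = FALSE]
  v <- stats::lm.fit(Z, tr)$residuals            # annihilated treatment col
  vv <- sum(v^2)
  tcrit <- stats::qt(1 - alpha / 2, df)
  with_seed(scenario$seed, {
    b <- matrix(stats::rnorm(reps * C, 0, csd), C, reps)
    pe <- matrix(stats::rnorm(reps * P, 0, psd), P, reps)
    eps <- matrix(stats::rnorm(reps * C * P, 0, sd_cp), C * P, reps)
    Y <- tm$baseline_mean + effect * tr + b[cl, ] + pe[per, ] + eps
    est <- drop(crossprod(v, Y)) / vv
    res <- qr.resid(qrX, Y)
    s2 <- colSums(res^2) / df
    tstat <- est / sqrt(s2 / vv)
    rej <- abs(tstat) > tcrit
    n_treated_cp <- sum(tr)
    simulation_summary(
      design = "stepped_wedge", n_reps = reps, alpha = alpha,
      rejection_rate = mean(rej),
      person_time = c(placebo = (C * P - n_treated_cp) * m * pw,
                      active = n_treated_cp * m * pw,
                      unexposed = 0),
      total_follow_up = C * P * m * pw,
      proportion_ever_active = 1,
      mean_n_randomized = C * m,
      allocation = NULL,
      extras = list(final_period_treated = mean(treated[, P]),
                    schedule = treated))
  })
}

#' Simulate a randomised-withdrawal trial
#'
#' All patients receive open-label active treatment during a run-in;
#' responders are then randomised 1:1 to continue active treatment or
#' switch to placebo, and relapse rates are compared with the pooled
#' two-proportion z-test. Only responders randomised to placebo accrue
#' placebo person-time. Replicates with fewer than one patient per
#' randomised group are non-informative.
#'
#' @param scenario A \code{\link{trial_scenario}} with a \code{binary}
#'   model whose \code{active} arm gives the run-in response probability,
#'   \code{p_relapse} (named: \code{active}, \code{placebo}),
#'   \code{n_patients}, \code{run_in_weeks} and
#'   \code{phase2_relapse_weeks}.
#' @return A \code{\link{simulation_summary}}.
#' @export
simulate_withdrawal <- function(scenario) {
  stopifnot(inherits(scenario, "trial_scenario"))
  bm <- scenario$binary
  pr <- scenario$p_relapse
  N <- scenario$n_patients
  stopifnot(!is.null(bm), !is.null(pr), !is.null(N),
            all(c("active", "placebo") %in% names(pr)))
  p_resp <- unname(bm$p_success["active"])
  d1 <- scenario$run_in_weeks %||% scenario$period_weeks
  d2 <- scenario$phase2_relapse_weeks %||% scenario$period_weeks
  reps <- scenario$n_reps; alpha <- scenario$alpha
  with_seed(scenario$seed, {
    R <- stats::rbinom(reps, N, p_resp)
    extra <- stats::rbinom(reps, 1, 0.5)         # odd responder's arm
    n1 <- R %/% 2 + (R %% 2) * extra
    n2 <- R - n1
    informative <- n1 >= 1 & n2 >= 1
    y1 <- stats::rbinom(reps, n1, pr["active"])
    y2 <- stats::rbinom(reps, n2, pr["placebo"])
    rej <- two_prop_z(y1, pmax(n1, 1), y2, pmax(n2, 1), alpha)$reject
    simulation_summary(
      design = "randomized_withdrawal", n_reps = reps, alpha = alpha,
      rejection_rate = mean(rej[informative]),
      n_informative = sum(informative),
      person_time = c(placebo = mean(n2) * d2,
                      active = N * d1 + mean(n1) * d2,
                      unexposed = 0),
      total_follow_up = N * d1 + mean(R) * d2,
      proportion_ever_active = 1,
      mean_n_randomized = mean(R),
      allocation = c(continue_active = 0.5, switch_placebo = 0.5),
      extras = list(mean_responders = mean(R),
                    noninformative = sum(!informative)))
  })
}

#' Simulate an early-escape trial
#'
#' Patients are randomised to active treatment or placebo and followed
#' over \code{horizon_periods} periods; a patient meeting the a-priori
#' failure criterion in a period escapes (exits) at the end of that
#' period. The primary analysis compares cumulative failure rates at the
#' horizon with the pooled two-proportion z-test; person-time on each arm
#' is truncated at escape.
#'
#' @param scenario A \code{\link{trial_scenario}} whose \code{binary}
#'   model gives the per-period failure probability of each arm (first
#'   arm = active, arm named \code{"placebo"} = control),
#'   \code{n_per_arm}, \code{horizon_periods} and \code{period_weeks}.
#' @return A \code{\link{simulation_summary}}.
#' @export
simulate_early_escape <- function(scenario) {
  stopifnot(inherits(scenario, "trial_scenario"))
  bm <- scenario$binary
  n <- scenario$n_per_arm
  H <- scenario$horizon_periods
  stopifnot(!is.null(bm), !is.null(n), !is.null(H), H >= 1)
  if (length(n) == 1) n <- rep(n, 2)
  q <- unname(bm$p_success[1:2])        # per-period failure probabilities
  reps <- scenario$n_reps; alpha <- scenario$alpha; pw <- scenario$period_weeks
  with_seed(scenario$seed, {
    at_risk <- cbind(rep(n[1], reps), rep(n[2], reps))
    fails <- matrix(0, reps, 2)
    ptime <- matrix(0, reps, 2)
    for (k in seq_len(H)) {
      for (a in 1:2) {
        ptime[, a] <- ptime[, a] + at_risk[, a] * pw
        f <- stats::rbinom(reps, at_risk[, a], q[a])
        fails[, a] <- fails[, a] + f
        at_risk[, a] <- at_risk[, a] - f
      }
    }
    rej <- two_prop_z(fails[, 1], n[1], fails[, 2], n[2], alpha)$reject
    is_plac <- names(bm$p_success)[1:2] == "placebo"
    pt <- colMeans(ptime)
    simulation_summary(
      design = "early_escape", n_reps = reps, alpha = alpha,
      rejection_rate = mean(rej),
      person_time = c(placebo = sum(pt[is_plac]),
                      active = sum(pt[!is_plac]),
                      unexposed = sum(n) * H * pw - sum(pt)),
      total_follow_up = sum(n) * H * pw,
      proportion_ever_active = n[!is_plac][1] / sum(n),
      mean_n_randomized = sum(n),
      allocation = stats::setNames(n / sum(n), names(bm$p_success)[1:2]),
      extras = list(mean_failures = colMeans(fails),
                    mean_escape_time = pt))
  })
}

#' Simulate a three-stage trial
#'
#' Stage 1 is a parallel placebo-controlled comparison of response rates.
#' Stage 2 randomises the stage-1 active-arm responders to continue
#' treatment or withdraw to placebo and compares relapse rates. Stage 3
#' gives open-label treatment to the stage-1 placebo non-responders; those
#' who respond are randomised in the same withdrawal fashion. The three
#' stage p-values (pooled two-proportion z-tests) are combined by
#' \code{\link{fisher_combine}}; the design rejects when the combined
#' p-value is below \code{alpha}. A stage with no evaluable patients
#' contributes p = 1 (conservative) and is flagged.
#'
#' @param scenario A \code{\link{trial_scenario}} with a \code{binary}
#'   response model (arms \code{active}, \code{placebo}),
#'   \code{p_relapse} (named: \code{active}, \code{placebo}),
#'   \code{n_per_arm}, and stage durations \code{run_in_weeks} (stages 1
#'   and 3 response phases) and \code{phase2_relapse_weeks} (withdrawal
#'   phases).
#' @return A \code{\link{simulation_summary}}; \code{extras} carries the
#'   mean stage p-values and the count of degenerate stages.
#' @export
simulate_three_stage <- function(scenario) {
  stopifnot(inherits(scenario, "trial_scenario"))
  bm <- scenario$binary
  pr <- scenario$p_relapse
  n <- scenario$n_per_arm
  stopifnot(!is.null(bm), !is.null(pr), !is.null(n),
            all(c("active", "placebo") %in% names(bm$p_success)),
            all(c("active", "placebo") %in% names(pr)))
  pa <- unname(bm$p_success["active"]); pp <- unname(bm$p_success["placebo"])
  d1 <- scenario$run_in_weeks %||% scenario$period_weeks
  d2 <- scenario$phase2_relapse_weeks %||% scenario$period_weeks
  reps <- scenario$n_reps; alpha <- scenario$alpha
  with_seed(scenario$seed, {
    # stage 1: parallel response comparison
    xa <- stats::rbinom(reps, n, pa)
    xp <- stats::rbinom(reps, n, pp)
    p1 <- two_prop_z(xa, n, xp, n)$p
    withdrawal_stage <- function(n_resp) {
      extra <- stats::rbinom(reps, 1, 0.5)
      n1 <- n_resp %/% 2 + (n_resp %% 2) * extra
      n2 <- n_resp - n1
      ok <- n1 >= 1 & n2 >= 1
      y1 <- stats::rbinom(reps, n1, pr["active"])
      y2 <- stats::rbinom(reps, n2, pr["placebo"])
      p <- two_prop_z(y1, pmax(n1, 1), y2, pmax(n2, 1))$p
      p[!ok] <- 1
      list(p = p, ok = ok, n1 = n1, n2 = n2)
    }
    s2 <- withdrawal_stage(xa)
    M <- n - xp                            # placebo non-responders
    r3 <- stats::rbinom(reps, M, pa)       # respond on open-label bridge
    s3 <- withdrawal_stage(r3)
    X <- -2 * (log(p1) + log(s2$p) + log(s3$p))
    pcomb <- stats::pchisq(X, df = 6, lower.tail = FALSE)
    rej <- pcomb < alpha
    pt_placebo <- n * d1 + mean(s2$n2) * d2 + mean(s3$n2) * d2
    pt_active <- n * d1 + mean(s2$n1) * d2 + mean(M) * d1 +
      mean(s3$n1) * d2
    simulation_summary(
      design = "three_stage", n_reps = reps, alpha = alpha,
      rejection_rate = mean(rej),
      person_time = c(placebo = pt_placebo, active = pt_active,
                      unexposed = 0),
      total_follow_up = pt_placebo + pt_active,
      proportion_ever_active = (n + mean(M)) / (2 * n),
      mean_n_randomized = 2 * n,
      allocation = c(active = 0.5, placebo = 0.5),
      extras = list(mean_p = c(stage1 = mean(p1), stage2 = mean(s2$p),
                               stage3 = mean(s3$p)),
                    stage_rejections = c(stage1 = mean(p1 < alpha),
                                         stage2 = mean(s2$p < alpha),
                                         stage3 = mean(s3$p < alpha)),
                    degenerate_stages = sum(!s2$ok) + sum(!s3$ok),
                    combined_p = pcomb))
  })
}

#' Dispatch a scenario to its design's simulator
#'
#' @param scenario A \code{\link{trial_scenario}}.
#' @return A \code{\link{simulation_summary}}.
#' @export
simulate_design <- function(scenario) {
  stopifnot(inherits(scenario, "trial_scenario"))
  switch(scenario$design,
         parallel = simulate_parallel(scenario),
         factorial = simulate_factorial(scenario),
         crossover = simulate_within_patient(scenario, "crossover"),
         latin_square = simulate_within_patient(scenario, "latin_square"),
         n_of_1 = simulate_within_patient(scenario, "n_of_1"),
         delayed_start = simulate_delayed_start(scenario),
         placebo_phase = simulate_placebo_phase(scenario),
         stepped_wedge = simulate_stepped_wedge(scenario),
         randomized_withdrawal = simulate_withdrawal(scenario),
         early_escape = simulate_early_escape(scenario),
         three_stage = simulate_three_stage(scenario),
         adaptive_randomization = simulate_adaptive(
           scenario$rule %||% "PW", scenario$binary,
           n_patients = scenario$n_patients, n_reps = scenario$n_reps,
           seed = scenario$seed, initial = scenario$initial_urn,
           alpha = scenario$alpha, period_weeks = scenario$period_weeks))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
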