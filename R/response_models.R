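#' Binary (success/failure) patient-response model
#'
#' Bernoulli response per patient-period, with an arm-specific success
#' probability and an optional first-order carry-over: when a patient's
#' immediately preceding period was on an active arm, \code{carryover} is
#' added to the success probability (clipped to [0, 1]).
#'
#' @param p_success Named numeric vector of success probabilities, one per
#'   arm. An arm named \code{"placebo"} is treated as inactive for
#'   carry-over purposes; all other arms are active.
#' @param carryover Additive probability shift applied when the previous
#'   period was active. Default 0.
#' @return An object of class \code{binary_model}.
#' @examples
#' binary_model(c(active = 0.8, placebo = 0.3))
#' @export
binary_model <- function(p_success, carryover = 0) {
  stopifnot(is.numeric(p_success), length(p_success) >= 1,
            all(p_success >= 0), all(p_success <= 1),
            is.numeric(carryover), length(carryover) == 1)
  if (is.null(names(p_success)))
    names(p_success) <- paste0("arm", seq_along(p_success))
  structure(list(p_success = p_success, carryover = carryover,
                 active = names(p_success) != "placebo"),
            class = "binary_model")
}

#' Continuous score-trajectory model
#'
#' Scores evolve linearly in time with a treatment-dependent slope (in score
#' units per week), an optional immediate symptomatic offset under active
#' treatment, a patient-level baseline, and residuals that are
#' equicorrelated within patient (shared random intercept), with
#' correlation \code{rho}. Higher scores are read as more severe disease
#' (as for clinical rating scales), so a beneficial treatment has a smaller
#' slope and/or a negative symptomatic offset.
#'
#' @param baseline_mean,baseline_sd Mean and s.d. of the patient baseline
#'   score. \code{baseline_sd >= 0}.
#' @param slope_active,slope_placebo Score change per week on active
#'   treatment / on placebo.
#' @param residual_sd S.d. of the visit-level residual (>= 0).
#' @param rho Within-patient correlation of residuals, in [0, 1).
#' @param symptomatic_offset Immediate score shift while on active
#'   treatment (0 = purely disease-modifying effect).
#' @param carryover Additive score shift in a period immediately following
#'   an active period (used by within-patient designs without washout).
#' @return An object of class \code{trajectory_model}.
#' @export
trajectory_model <- function(baseline_mean = 0, baseline_sd = 0,
                             slope_active = 0, slope_placebo = 0,
                             residual_sd = 1, rho = 0,
                             symptomatic_offset = 0, carryover = 0) {
  stopifnot(baseline_sd >= 0, residual_sd >= 0, rho >= 0, rho < 1)
  structure(list(baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 slope_active = slope_active, slope_placebo = slope_placebo,
                 residual_sd = residual_sd, rho = rho,
                 symptomatic_offset = symptomatic_offset,
                 carryover = carryover),
            class = "trajectory_model")
}

#' Response-latency model
#'
#' Time to response follows a piecewise-exponential distribution: hazard
#' \code{hazard_untreated} (events/week) before active treatment starts and
#' \code{hazard_treated} afterwards. With an effective treatment
#' (\code{hazard_treated > hazard_untreated}), patients who start
#' treatment earlier respond sooner on average.
#'
#' @param hazard_untreated,hazard_treated Non-negative hazards (per week).
#' @return An object of class \code{latency_model}.
#' @export
latency_model <- function(hazard_untreated, hazard_treated) {
  stopifnot(is.numeric(hazard_untreated), hazard_untreated >= 0,
            is.numeric(hazard_treated), hazard_treated >= 0)
  structure(list(hazard_untreated = hazard_untreated,
                 hazard_treated = hazard_treated),
            class = "latency_model")
}

#' Generate binary outcomes for an assignment matrix
#'
#' @param model A \code{\link{binary_model}}.
#' @param assignments Character matrix (patients x periods) of arm names, or
#'   a character vector for a single-period trial. \code{NA} marks periods
#'   in which a patient is not observed.
#' @param seed Integer seed; the generator is a pure function of
#'   (model, assignments, seed).
#' @return Integer matrix (patients x periods) of 0/1 outcomes, \code{NA}
#'   where unobserved.
#' @examples
#' m <- binary_model(c(active = 0.8, placebo = 0.3))
#' generate_binary_outcomes(m, c("active", "placebo", "active"), seed = 1)
#' @export
generate_binary_outcomes <- function(model, assignments, seed) {
  stopifnot(inherits(model, "binary_model"))
  if (!is.matrix(assignments)) assignments <- matrix(assignments, ncol = 1)
  known <- assignments %in% names(model$p_success) | is.na(assignments)
  if (!all(known))
    stop("undefined arm(s): ",
         paste(unique(assignments[!known]), collapse = ", "),
         "; model defines: ", paste(names(model$p_success), collapse = ", "),
         call. = FALSE)
  p <- matrix(model$p_success[assignments], nrow = nrow(assignments))
  if (model$carryover != 0 && ncol(assignments) > 1) {
    act <- matrix(model$active[match(assignments, names(model$p_success))],
                  nrow = nrow(assignments))
    prev_active <- cbind(FALSE, act[, -ncol(act), drop = FALSE])
    p <- p + model$carryover * (prev_active & !is.na(p))
    p <- pmin(pmax(p, 0), 1)
  }
  with_seed(seed, {
    out <- matrix(NA_integer_, nrow(p), ncol(p))
    obs <- !is.na(p)
    out[obs] <- stats::rbinom(sum(obs), 1L, p[obs])
    out
  })
}

#' Generate correlated score trajectories
#'
#' The expected score of patient i at visit time t is
#' \code{baseline + symptomatic_offset * on_active(t) + integral of the
#' applicable slope up to t}; residuals share a patient-level intercept so
#' that any two visits of the same patient have correlation \code{rho}.
#'
#' @param model A \code{\link{trajectory_model}}.
#' @param on_active Logical matrix (patients x visits): is patient i on
#'   active treatment during the interval ending at visit j (and at visit
#'   j itself, for the symptomatic offset)? A single logical vector is
#'   recycled across patients.
#' @param visit_times Strictly increasing visit times (weeks); the first
#'   interval runs from time 0.
#' @param seed Integer seed.
#' @return Numeric matrix (patients x visits) of scores.
#' @export
generate_trajectories <- function(model, on_active, visit_times, seed) {
  stopifnot(inherits(model, "trajectory_model"))
  if (any(diff(c(0, visit_times)) <= 0))
    stop("visit times must be strictly increasing and positive", call. = FALSE)
  if (!is.matrix(on_active))
    on_active <- matrix(on_active, nrow = 1)
  if (ncol(on_active) != length(visit_times))
    stop("on_active must have one column per visit", call. = FALSE)
  n <- nrow(on_active); v <- length(visit_times)
  dt <- diff(c(0, visit_times))
  slope <- ifelse(on_active, model$slope_active, model$slope_placebo)
  incr <- sweep(slope, 2, dt, `*`)
  drift <- if (v > 1) t(apply(incr, 1, cumsum)) else incr
  if (!is.matrix(drift) || nrow(drift) != n) drift <- matrix(drift, n, v, byrow = n == 1)
  mean_mat <- model$baseline_mean + drift +
    model$symptomatic_offset * on_active
  with_seed(seed, {
    b <- stats::rnorm(n, 0, model$baseline_sd)
    u <- stats::rnorm(n, 0, sqrt(model$rho) * model$residual_sd)
    e <- matrix(stats::rnorm(n * v, 0, sqrt(1 - model$rho) * model$residual_sd),
                n, v)
    mean_mat + b + u + e
  })
}

#' Generate response latencies under a piecewise-constant hazard
#'
#' Each patient's hazard is \code{hazard_untreated} before their
#' \code{start_of_active} time and \code{hazard_treated} after it; the
#' response time is drawn by inverting the cumulative hazard.
#'
#' @param model A \code{\link{latency_model}}.
#' @param start_of_active Non-negative vector of active-treatment start
#'   times (weeks), one per patient.
#' @param seed Integer seed.
#' @return Numeric vector of response times (weeks); \code{Inf} when both
#'   hazards are 0 past the relevant ranges.
#' @export
generate_latencies <- function(model, start_of_active, seed) {
  stopifnot(inherits(model, "latency_model"))
  if (any(start_of_active < 0))
    stop("start_of_active times must be non-negative", call. = FALSE)
  h0 <- model$hazard_untreated; h1 <- model$hazard_treated
  with_seed(seed, {
    ee <- stats::rexp(length(start_of_active))
    cum_at_start <- h0 * start_of_active
    t <- ifelse(ee < cum_at_start,
                ee / h0,
                if (h1 > 0) start_of_active + (ee - cum_at_start) / h1 else Inf)
    # h0 == 0: cum_at_start = 0, branch above handles it (ee < 0 impossible)
    t
  })
}

# evaluate expr with a local, restored RNG state seeded at seed
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
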