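#' Urn state for response-adaptive randomisation
#'
#' The urn holds one (possibly fractional) ball count per treatment, plus an
#' immigration-ball count used by the drop-the-loser rule (0 for
#' play-the-winner). Draw probabilities are proportional to ball counts.
#' Fractional treatment counts arise from the play-the-winner failure rule,
#' which partitions one ball across the other arms proportionally.
#'
#' @param treatment Non-negative numeric vector of treatment ball counts
#'   (one per arm); names are kept if present.
#' @param immigration Non-negative immigration ball count (default 0).
#' @return An object of class \code{urn_state}.
#' @examples
#' urn_state(c(1, 1))                 # play-the-winner start
#' urn_state(c(1, 1), immigration = 1)  # drop-the-loser start
#' @export
urn_state <- function(treatment, immigration = 0) {
  stopifnot(is.numeric(treatment), length(treatment) >= 1,
            all(treatment >= 0), is.numeric(immigration),
            length(immigration) == 1, immigration >= 0)
  if (is.null(names(treatment)))
    names(treatment) <- paste0("arm", seq_along(treatment))
  structure(list(treatment = treatment, immigration = immigration),
            class = "urn_state")
}

#' @export
print.urn_state <- function(x, ...) {
  cat("Urn:", paste(sprintf("%s=%.3g", names(x$treatment), x$treatment),
                    collapse = ", "))
  if (x$immigration > 0) cat(" | immigration =", x$immigration)
  cat("\n")
  invisible(x)
}

#' Draw one ball from the urn (with replacement)
#'
#' @param urn An \code{\link{urn_state}} with positive total count.
#' @return The index of the drawn treatment arm, or \code{0} for an
#'   immigration ball. The urn itself is unchanged by the draw.
#' @export
urn_draw <- function(urn) {
  stopifnot(inherits(urn, "urn_state"))
  tot <- sum(urn$treatment) + urn$immigration
  if (tot <= 0) stop("cannot draw from an empty urn", call. = FALSE)
  u <- stats::runif(1) * tot
  cum <- cumsum(urn$treatment)
  i <- findInterval(u, cum, left.open = TRUE) + 1L
  if (i > length(urn$treatment)) 0L else i
}

#' Play-the-winner urn update
#'
#' A success on arm i adds one ball of type i. A failure on arm i adds one
#' ball partitioned across the other arms in proportion to their current
#' counts (arm i excluded). The total ball count therefore grows by exactly
#' one per treated patient.
#'
#' @param urn A play-the-winner \code{\link{urn_state}} (no immigration
#'   balls).
#' @param arm Index of the treated arm.
#' @param success Logical outcome.
#' @return The updated \code{urn_state}.
#' @examples
#' u <- urn_state(c(1, 1))
#' pw_update(u, 1, TRUE)$treatment    # 2, 1
#' pw_update(urn_state(c(2, 2)), 1, FALSE)$treatment  # 2, 3
#' @export
pw_update <- function(urn, arm, success) {
  stopifnot(inherits(urn, "urn_state"), urn$immigration == 0,
            arm >= 1, arm <= length(urn$treatment),
            is.logical(success), length(success) == 1)
  if (success) {
    urn$treatment[arm] <- urn$treatment[arm] + 1
  } else {
    others <- setdiff(seq_along(urn$treatment), arm)
    tot <- sum(urn$treatment[others])
    if (tot <= 0)
      stop("play-the-winner failure partition undefined: ",
           "all other arms have zero balls", call. = FALSE)
    urn$treatment[others] <- urn$treatment[others] +
      urn$treatment[others] / tot
  }
  urn
}

#' Drop-the-loser urn update
#'
#' A failure on a treatment arm removes one ball of that type (floored at
#' zero); a success leaves the urn unchanged. When an immigration ball is
#' drawn, one ball of every treatment type is added (the immigration count
#' itself never changes) and no patient is assigned — the caller redraws.
#'
#' @param urn A drop-the-loser \code{\link{urn_state}} with
#'   \code{immigration > 0}.
#' @param drawn Index of the drawn ball type: a treatment index, or 0 for
#'   immigration.
#' @param success Logical outcome of the treated patient; ignored for an
#'   immigration draw.
#' @return The updated \code{urn_state}.
#' @export
dl_update <- function(urn, drawn, success = NA) {
  stopifnot(inherits(urn, "urn_state"), urn$immigration > 0,
            drawn >= 0, drawn <= length(urn$treatment))
  if (drawn == 0) {
    urn$treatment <- urn$treatment + 1
  } else if (!is.na(success) && !success) {
    urn$treatment[drawn] <- max(urn$treatment[drawn] - 1, 0)
  }
  urn
}

#' Simulate a response-adaptive (urn-randomised) trial
#'
#' Patients accrue sequentially; each is assigned by drawing from the urn
#' (redrawing after immigration draws under drop-the-loser), their binary
#' outcome is observed immediately, and the urn is updated by the
#' play-the-winner or drop-the-loser rule before the next patient arrives.
#' The primary analysis compares success proportions between the first two
#' arms with the pooled two-proportion z-test; replicates in which an arm
#' has no patients are non-informative.
#'
#' @param rule \code{"PW"} (play-the-winner) or \code{"DL"}
#'   (drop-the-loser).
#' @param model A \code{\link{binary_model}}; one probability per arm.
#' @param n_patients Number of sequentially assigned patients.
#' @param n_reps Number of Monte-Carlo replicates.
#' @param seed Integer seed.
#' @param initial Optional initial \code{\link{urn_state}}; defaults to one
#'   ball per arm (plus one immigration ball for DL).
#' @param alpha Two-sided test size.
#' @param period_weeks Length of the treatment period per patient (weeks),
#'   used for person-time accounting.
#' @return A \code{\link{simulation_summary}}. The \code{extras} component
#'   carries \code{allocation_prop_reps} (replicate-level allocation
#'   proportion of arm 1) and \code{mean_failures}.
#' @export
simulate_adaptive <- function(rule = c("PW", "DL"), model, n_patients,
                              n_reps = 1000, seed = 1, initial = NULL,
                              alpha = 0.05, period_weeks = 1) {
  rule <- match.arg(rule)
  stopifnot(inherits(model, "binary_model"), n_patients >= 1)
  k <- length(model$p_success)
  if (is.null(initial)) {
    initial <- urn_state(stats::setNames(rep(1, k), names(model$p_success)),
                         immigration = if (rule == "DL") 1 else 0)
  }
  stopifnot(length(initial$treatment) == k)
  p <- unname(model$p_success)
  with_seed(seed, {
    alloc <- matrix(0L, n_reps, k)
    succ <- matrix(0L, n_reps, k)
    prop1 <- numeric(n_reps)
    for (r in seq_len(n_reps)) {
      urn <- initial
      n_arm <- integer(k); s_arm <- integer(k)
      for (pt in seq_len(n_patients)) {
        repeat {
          d <- urn_draw(urn)
          if (d != 0L) break
          urn <- dl_update(urn, 0L)          # immigration: replenish, redraw
        }
        y <- stats::rbinom(1L, 1L, p[d]) == 1L
        n_arm[d] <- n_arm[d] + 1L
        s_arm[d] <- s_arm[d] + as.integer(y)
        urn <- if (rule == "PW") pw_update(urn, d, y) else dl_update(urn, d, y)
      }
      alloc[r, ] <- n_arm
      succ[r, ] <- s_arm
      prop1[r] <- n_arm[1] / n_patients
    }
    informative <- alloc[, 1] > 0 & alloc[, 2] > 0
    rej <- rep(NA, n_reps)
    rej[informative] <- two_prop_z(succ[informative, 1], alloc[informative, 1],
                                   succ[informative, 2], alloc[informative, 2],
                                   alpha)$reject
    failures <- rowSums(alloc) - rowSums(succ)
    is_placebo <- names(model$p_success) == "placebo"
    placebo_time <- mean(alloc[, is_placebo, drop = FALSE] %*%
                           rep(period_weeks, sum(is_placebo)))
    simulation_summary(
      design = "adaptive_randomization",
      n_reps = n_reps, alpha = alpha,
      rejection_rate = mean(rej[informative]),
      n_informative = sum(informative),
      person_time = c(placebo = placebo_time,
                      active = n_patients * period_weeks - placebo_time,
                      unexposed = 0),
      total_follow_up = n_patients * period_weeks,
      proportion_ever_active = mean(alloc[, !is_placebo, drop = FALSE] %*%
                                      rep(1, sum(!is_placebo))) / n_patients,
      mean_n_randomized = n_patients,
      allocation = stats::setNames(colMeans(alloc) / n_patients,
                                   names(model$p_success)),
      extras = list(allocation_prop_reps = prop1,
                    mean_failures = mean(failures),
                    rule = rule))
  })
}
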