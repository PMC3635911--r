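# Independent oracles used across the suite. These re-derive expected values
# by enumeration or closed form and never call the code paths they check.

# exact rejection probability of the pooled two-proportion z-test by
# exhaustive binomial enumeration
oracle_two_prop_size <- function(n1, n2, p1, p2, alpha = 0.05) {
  if (n1 < 1 || n2 < 1) return(0)
  zcrit <- qnorm(1 - alpha / 2)
  tot <- 0
  for (x1 in 0:n1) {
    px1 <- dbinom(x1, n1, p1)
    x2 <- 0:n2
    px2 <- dbinom(x2, n2, p2)
    pp <- (x1 + x2) / (n1 + n2)
    se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    zz <- ifelse(se > 0, abs(x1 / n1 - x2 / n2) / se, 0)
    tot <- tot + px1 * sum(px2[zz > zcrit])
  }
  tot
}

# closed-form normal-approximation power for a two-sided two-proportion
# comparison (pooled-null form)
oracle_normal_power <- function(p1, p2, n, alpha = 0.05) {
  pb <- (p1 + p2) / 2
  se0 <- sqrt(2 * pb * (1 - pb) / n)
  se1 <- sqrt(p1 * (1 - p1) / n + p2 * (1 - p2) / n)
  pnorm((abs(p1 - p2) - qnorm(1 - alpha / 2) * se0) / se1)
}

# brute-force design selection by direct attribute filtering of the
# registry table (vectorised logic, independent of the engine's node loop)
oracle_select <- function(reversible, speed, minpl, allact, comp) {
  reg <- smalltrial::design_registry()
  keep <- rep(TRUE, nrow(reg))
  if (!reversible) keep <- keep & !reg$requires_reversible_outcome
  if (speed == "slow") keep <- keep & !reg$requires_fast_response
  if (minpl == "required") {
    ok <- reg$minimizes_time_on_placebo
    if (speed == "slow")
      ok <- ok & !reg$placebo_minimization_requires_fast_response
    keep <- keep & ok
  }
  if (allact == "required") keep <- keep & reg$all_patients_active_at_end
  if (comp != "indifferent") keep <- keep & reg$comparison_basis == comp
  reg$name[keep]
}

# exact allocation distribution (number of patients on arm 1) for the
# two-arm randomised play-the-winner urn, by full tree enumeration
oracle_pw_alloc <- function(n, p, init = c(1, 1)) {
  dist <- numeric(n + 1)
  recurse <- function(urn, left, n1, prob) {
    if (left == 0) {
      dist[n1 + 1] <<- dist[n1 + 1] + prob
      return(invisible())
    }
    tot <- sum(urn)
    for (arm in 1:2) {
      pdraw <- urn[arm] / tot
      if (pdraw <= 0) next
      for (succ in c(TRUE, FALSE)) {
        pout <- if (succ) p[arm] else 1 - p[arm]
        if (pout <= 0) next
        u2 <- urn
        if (succ) u2[arm] <- u2[arm] + 1
        else u2[3 - arm] <- u2[3 - arm] + 1   # K = 2: whole ball to other arm
        recurse(u2, left - 1, n1 + (arm == 1), prob * pdraw * pout)
      }
    }
  }
  recurse(init, n, 0, 1)
  dist
}

# exact allocation distribution for the two-arm drop-the-loser urn with one
# immigration ball; immigration redraws are absorbed analytically
oracle_dl_alloc <- function(n, p, init = c(1, 1), imm = 1, mmax = 80) {
  dist <- numeric(n + 1)
  assign_probs <- function(urn) {
    # P(assigned arm i after m immigration draws), m = 0..mmax
    out <- list()
    pstay <- 1
    for (m in 0:mmax) {
      tot <- sum(urn) + 2 * m + imm
      for (arm in 1:2) {
        pa <- pstay * (urn[arm] + m) / tot
        if (pa > 1e-14)
          out[[length(out) + 1]] <- list(arm = arm, p = pa,
                                         urn = urn + m)
      }
      pstay <- pstay * imm / tot
      if (pstay < 1e-14) break
    }
    out
  }
  recurse <- function(urn, left, n1, prob) {
    if (left == 0) {
      dist[n1 + 1] <<- dist[n1 + 1] + prob
      return(invisible())
    }
    for (br in assign_probs(urn)) {
      arm <- br$arm
      for (succ in c(TRUE, FALSE)) {
        pout <- if (succ) p[arm] else 1 - p[arm]
        if (pout <= 0) next
        u2 <- br$urn
        if (!succ) u2[arm] <- max(u2[arm] - 1, 0)
        recurse(u2, left - 1, n1 + (arm == 1), prob * br$p * pout)
      }
    }
  }
  recurse(init, n, 0, 1)
  dist
}

# shorthand: is a Monte-Carlo rate within 3 binomial standard errors of a
# reference value?
within_3se <- function(rate, target, n_reps) {
  se <- sqrt(max(rate * (1 - rate), 1e-12) / n_reps)
  abs(rate - target) <= 3 * se
}
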