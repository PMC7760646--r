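# Independent oracles used across the suite.  These deliberately avoid the
# package's own solver paths: the linear profile comes from the matrix
# exponential of the two-compartment system, and likelihood references are
# literal transcriptions of the Gaussian density.

# Closed-form linear two-compartment infusion profile (free amounts), valid
# when Rtot = Rtotp = 0 and Smax = 0.  Piecewise constant-input solution via
# eigen decomposition of the rate matrix.
linear2cpt_amounts <- function(CL, V1, V2, Q, dose, dur, times) {
  M <- matrix(c(-(CL + Q) / V1, Q / V2,
                Q / V1, -Q / V2), 2L, 2L, byrow = TRUE)
  eg <- eigen(M)
  P <- eg$vectors
  Pinv <- solve(P)
  lam <- eg$values
  propagate <- function(A0, u, t) {
    # A(t) = e^{Mt} A0 + M^{-1} (e^{Mt} - I) u  for constant input u
    elt <- exp(lam * t)
    EM <- P %*% diag(elt, 2L) %*% Pinv
    if (all(u == 0)) {
      as.numeric(EM %*% A0)
    } else {
      as.numeric(EM %*% A0 + P %*% diag((elt - 1) / lam, 2L) %*% Pinv %*% u)
    }
  }
  rate <- dose / dur
  t(vapply(times, function(t) {
    if (t <= dur) {
      propagate(c(0, 0), c(rate, 0), t)
    } else {
      A_end <- propagate(c(0, 0), c(rate, 0), dur)
      propagate(A_end, c(0, 0), t - dur)
    }
  }, numeric(2L)))
}

# Literal hand transcription of the three model equations, kept independent
# of the compiled right-hand side.
hand_rhs <- function(state, p, rate) {
  A1 <- state[1L]; A2 <- state[2L]; A3 <- state[3L]
  C1 <- A1 / p$V1
  C2 <- A2 / p$V2
  dA1 <- (rate - (p$CL * A3 / p$V1 + p$Q / p$V1) * A1 + (p$Q / p$V2) * A2 -
            p$kint * p$Rtot * A1 / (p$Kss + C1)) /
    (1 + p$Rtot * p$Kss / (p$Kss + C1)^2)
  dA2 <- ((p$Q / p$V1) * A1 - (p$Q / p$V2) * A2) /
    (1 + p$Rtotp * p$Kss / (p$Kss + C2)^2)
  dA3 <- p$kout * (1 + p$Smax * C1^p$gamma / (p$S50^p$gamma + C1^p$gamma)) -
    p$kout * A3
  c(dA1, dA2, dA3)
}

# A small trial design used to keep fitting tests quick: 2 subjects per
# cohort, full sampling schedule.
small_design <- function(n_per_cohort = 2) {
  trial_design(n_per_cohort = n_per_cohort)
}

# Control settings for fitting tests: start from the truth, skip the simplex
# phase, cap the gradient phase.
fast_ctl <- function(...) {
  modifyList(list(simplex_maxit = 0L, bfgs_maxit = 30L, rel_tol = 1e-7), list(...))
}

# Fixed mask used in the small-sample fitting tests: the published values of
# the binding constants and the Hill coefficient (never estimated here) plus
# the weakly identified distribution parameters Q and V2.
fix_small <- c("Kss", "kint", "Rtot", "gamma", "Q", "V2")
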