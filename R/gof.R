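#' Goodness-of-fit residual table
#'
#' Per-observation population and individual predictions plus weighted
#' residuals: IWRES = (log y - log C_ind)/sigma at the empirical Bayes
#' estimates, and a conditional weighted residual (CWRES) from first-order
#' linearization of the log-prediction around the EBEs, whitened by the
#' implied marginal covariance `G Omega G' + sigma^2 I`.
#'
#' @param data the dataset the model was fitted to.
#' @param fit a converged `nimo_fit`.
#' @return Data frame with columns ID, TIME, DV, PRED, IPRED, IWRES, CWRES.
#' @export
gof_residuals <- function(data, fit) {
  stopifnot(inherits(fit, "nimo_fit"))
  if (data_hash(data) != fit$data_hash) {
    stop("'data' is not the dataset this model was fitted to")
  }
  if (is.null(fit$ebe)) stop("fit carries no empirical Bayes estimates")
  ld <- build_likelihood_data(data)
  p <- fit$estimates
  pm <- build_pmat(ld, p, fit$covariate_model)
  omegas <- c(p$omega_Rtotp, p$omega_kout)
  sig <- p$sigma_log

  pred_at <- function(pv, eta, s) {
    pv["Rtotp"] <- pv["Rtotp"] * exp(eta[1L])
    pv["kout"] <- pv["kout"] * exp(eta[2L])
    st <- .tmdd_solve_cpp(pv, s$doses$amount, s$doses$start,
                          s$doses$duration, s$obs$time, 1e-8, 1e-10)
    C1 <- st[, 1L] / pv["V1"]
    pmax(C1 + pv["Rtot"] * C1 / (pv["Kss"] + C1), 1e-300)
  }

  out <- vector("list", ld$n)
  for (i in seq_len(ld$n)) {
    s <- ld$subs[[i]]
    m <- nrow(s$obs)
    if (m == 0L) next
    pv <- pm[i, ]
    eta <- fit$ebe[i, ]
    lp0 <- log(pred_at(pv, c(0, 0), s))
    lpi <- log(pred_at(pv, eta, s))
    iwres <- (log(s$obs$conc) - lpi) / sig

    # FD gradient of the log individual prediction wrt eta at the EBE.
    G <- matrix(0, m, 2L)
    for (k in 1:2) {
      if (omegas[k] == 0) next
      h <- 1e-4 * (1 + abs(eta[k]))
      ep <- eta; ep[k] <- eta[k] + h
      em <- eta; em[k] <- eta[k] - h
      G[, k] <- (log(pred_at(pv, ep, s)) - log(pred_at(pv, em, s))) / (2 * h)
    }
    r <- log(s$obs$conc) - lpi + as.numeric(G %*% eta)
    V <- G %*% diag(omegas^2, 2L) %*% t(G) + diag(sig^2, m)
    cw <- backsolve(chol(V), r, transpose = TRUE)
    out[[i]] <- data.frame(ID = s$id, TIME = s$obs$time, DV = s$obs$conc,
                           PRED = exp(lp0), IPRED = exp(lpi),
                           IWRES = iwres, CWRES = cw)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
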