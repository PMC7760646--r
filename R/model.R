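#' ODE right-hand side of the QSS TMDD model
#'
#' Evaluates the time derivative of the state (free central amount A1 in mg,
#' free peripheral amount A2 in mg, mediator level A3, dimensionless) at a
#' given infusion rate. Drug in each binding compartment exchanges with a
#' target pool held at constant total concentration under the
#' quasi-steady-state approximation; this contributes the correction
#' denominators `1 + Rtot*Kss/(Kss + C)^2` (always >= 1) that divide the
#' free-drug material balance. The mediator is a turnover quantity whose
#' synthesis is stimulated by the free central concentration through a
#' sigmoid function and which multiplies the non-specific clearance.
#'
#' @param state numeric vector `c(A1, A2, A3)`.
#' @param p a `nimo_params` object.
#' @param infusion_rate zero-order drug input rate into the central
#'   compartment (mg/h).
#' @return Numeric vector `c(dA1, dA2, dA3)` (per hour).
#' @export
tmdd_rhs <- function(state, p, infusion_rate = 0) {
  validate_params(p)
  if (length(state) != 3L || any(!is.finite(state))) {
    stop("'state' must be a finite numeric vector (A1, A2, A3)")
  }
  if (!is.finite(infusion_rate) || infusion_rate < 0) {
    stop("'infusion_rate' must be finite and non-negative")
  }
  d <- .tmdd_rhs_cpp(param_vector(p), as.numeric(state), infusion_rate)
  names(d) <- c("A1", "A2", "A3")
  d
}

#' Total drug concentration in the central compartment
#'
#' The assay observable: free concentration plus the QSS-bound complex,
#' `C + Rtot * C / (Kss + C)` with `C = A1/V1`. The bound part saturates at
#' `Rtot`, so total - free is always below `Rtot` and the observable is
#' strictly increasing in the free amount.
#'
#' @param A1 free drug amount in the central compartment (mg); vectorized.
#' @param p a `nimo_params` object.
#' @return Total concentration in mg/L.
#' @export
total_concentration <- function(A1, p) {
  validate_params(p)
  if (any(!is.finite(A1)) || any(A1 < 0)) {
    stop("'A1' must be non-negative and finite")
  }
  C <- A1 / p$V1
  C + p$Rtot * C / (p$Kss + C)
}
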