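#' Stepwise covariate model building
#'
#' Univariate forward inclusion / backward elimination of parameter-covariate
#' relationships on top of a converged base fit. Continuous covariates enter
#' as power functions centered on the data median, categorical covariates as
#' fractional shifts. A candidate is added when it drops the OFV by at least
#' the chi-square criterion at `forward_alpha` (3.84 for alpha = 0.05,
#' 1 df) and survives elimination when its removal raises the OFV by at
#' least the criterion at `backward_alpha` (6.63 for alpha = 0.01).
#'
#' Parameters that carry a random effect are screened only when their
#' eta-shrinkage in the base fit is below `shrinkage_gate` percent: above
#' that, the empirical Bayes estimates are too shrunken for covariate
#' relationships to be meaningful. Parameters without a random effect are
#' always eligible.
#'
#' @param data a `nimo_trial` dataset.
#' @param base the base `nimo_fit` (no covariates).
#' @param covariates covariate column names to screen; categorical columns
#'   (`SEX`, `RACE`) use fractional shifts.
#' @param parameters structural parameter names to screen covariates on.
#' @param forward_alpha,backward_alpha significance levels of the forward
#'   and backward chi-square criteria (1 df each).
#' @param shrinkage_gate eta-shrinkage threshold in percent.
#' @param control fit control passed to the candidate fits.
#' @return List of class `nimo_scm`: `selected` (list of covariate terms in
#'   the final model), `final` (the final `nimo_fit`), `trace` (data frame
#'   of every step tested), `skipped` (parameters excluded by the gate),
#'   `reason` (non-NULL when screening could not run).
#' @export
scm <- function(data, base, covariates, parameters,
                forward_alpha = 0.05, backward_alpha = 0.01,
                shrinkage_gate = 35, control = list()) {
  stopifnot(inherits(base, "nimo_fit"))
  if (!identical(base$data_hash, data_hash(data))) {
    stop("'base' was not fitted to 'data'")
  }
  categorical <- c("SEX", "RACE")
  fwd_thr <- qchisq(1 - forward_alpha, 1)
  bwd_thr <- qchisq(1 - backward_alpha, 1)

  eta_map <- c(Rtotp = "eta_Rtotp", kout = "eta_kout")
  skipped <- character(0)
  eligible <- character(0)
  for (pm in parameters) {
    if (pm %in% names(eta_map)) {
      shr <- base$eta_shrinkage[[eta_map[[pm]]]]
      if (is.finite(shr) && shr >= shrinkage_gate) {
        skipped <- c(skipped, pm)
        next
      }
    }
    eligible <- c(eligible, pm)
  }
  if (!length(eligible)) {
    return(structure(list(selected = list(), final = base,
                          trace = data.frame(), skipped = skipped,
                          reason = "no eligible parameter (shrinkage gate)"),
                     class = "nimo_scm"))
  }

  make_term <- function(pm, cv) {
    covariate_term(pm, cv,
                   type = if (cv %in% categorical) "fractional" else "power",
                   theta = 0)
  }
  pairs <- expand.grid(param = eligible, cov = covariates,
                       stringsAsFactors = FALSE)

  fit_with <- function(terms) {
    nimo_fit(data, init = base$estimates, fix = base$fixed_mask,
             covariate_model = terms, control = control)
  }

  trace <- list()
  note <- function(phase, pm, cv, ofv, delta, thr, decision) {
    trace[[length(trace) + 1L]] <<- data.frame(
      phase = phase, param = pm, cov = cv, ofv = ofv, delta_ofv = delta,
      threshold = thr, decision = decision, stringsAsFactors = FALSE)
  }

  selected <- list()
  current <- base
  remaining <- pairs
  repeat {
    if (!nrow(remaining)) break
    best <- NULL
    best_delta <- -Inf
    for (k in seq_len(nrow(remaining))) {
      tm <- make_term(remaining$param[k], remaining$cov[k])
      cand <- tryCatch(fit_with(c(selected, list(tm))), error = function(e) NULL)
      if (is.null(cand)) {
        note("forward", remaining$param[k], remaining$cov[k], NA, NA,
             fwd_thr, "fit failed")
        next
      }
      delta <- current$ofv - cand$ofv
      sig <- is.finite(delta) && delta >= fwd_thr
      note("forward", remaining$param[k], remaining$cov[k], cand$ofv, delta,
           fwd_thr, if (sig) "significant" else "not significant")
      if (sig && delta > best_delta) {
        best <- list(term = tm, fit = cand, k = k)
        best_delta <- delta
      }
    }
    if (is.null(best)) break
    selected <- best$fit$covariate_model   # refitted thetas for all terms
    current <- best$fit
    remaining <- remaining[-best$k, , drop = FALSE]
  }

  # Backward elimination, least significant first.
  repeat {
    if (!length(selected)) break
    worst <- NULL
    worst_delta <- Inf
    for (j in seq_along(selected)) {
      reduced <- selected[-j]
      red_fit <- if (length(reduced)) {
        tryCatch(fit_with(reduced), error = function(e) NULL)
      } else {
        base
      }
      if (is.null(red_fit)) next
      delta <- red_fit$ofv - current$ofv
      note("backward", selected[[j]]$param, selected[[j]]$cov, red_fit$ofv,
           delta, bwd_thr, if (delta < bwd_thr) "removable" else "retained")
      if (delta < worst_delta) {
        worst <- list(j = j, fit = red_fit, delta = delta)
        worst_delta <- delta
      }
    }
    if (is.null(worst) || worst$delta >= bwd_thr) break
    selected <- selected[-worst$j]
    current <- worst$fit
  }

  structure(list(selected = selected, final = current,
                 trace = if (length(trace)) do.call(rbind, trace)
                         else data.frame(),
                 skipped = skipped, reason = NULL),
            class = "nimo_scm")
}

#' @export
print.nimo_scm <- function(x, ...) {
  if (!is.null(x$reason)) {
    cat("Covariate screening skipped:", x$reason, "\n")
    return(invisible(x))
  }
  if (!length(x$selected)) {
    cat("Covariate screening: no covariate retained\n")
  } else {
    cat("Covariate screening retained:\n")
    for (tm in x$selected) {
      cat(sprintf("  %s on %s (%s, theta = %.3f)\n", tm$cov, tm$param,
                  tm$type, tm$theta))
    }
  }
  if (length(x$skipped)) {
    cat("  gate-excluded parameters:", paste(x$skipped, collapse = ", "),
        "\n")
  }
  invisible(x)
}
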