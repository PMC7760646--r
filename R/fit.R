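# Population estimation: Laplace-approximated marginal likelihood with
# per-subject mode search over the random effects (eta on Rtotp and kout),
# outer optimisation on log-transformed parameters.

# Unconstrained transform for one parameter value.
par_transform <- function(name, value, mode) {
  if (name == "v1_dose50_change" && mode == "decrease") {
    stats::qlogis(value)
  } else {
    log(value)
  }
}

par_untransform <- function(name, tvalue, mode) {
  if (name == "v1_dose50_change" && mode == "decrease") {
    stats::plogis(tvalue)
  } else {
    exp(tvalue)
  }
}

# Flatten a dataset once into the arrays the compiled marginal expects.
build_likelihood_data <- function(data) {
  subs <- subject_records(data)
  n <- length(subs)
  obs_t <- obs_logdv <- dose_amt <- dose_start <- dose_dur <- numeric(0)
  obs_ptr <- dose_ptr <- integer(n + 1L)
  for (i in seq_len(n)) {
    s <- subs[[i]]
    if (any(!is.finite(s$obs$conc)) || any(s$obs$conc <= 0)) {
      stop("subject ", s$id, " has non-positive observed concentrations")
    }
    obs_t <- c(obs_t, s$obs$time)
    obs_logdv <- c(obs_logdv, log(s$obs$conc))
    dose_amt <- c(dose_amt, s$doses$amount)
    dose_start <- c(dose_start, s$doses$start)
    dose_dur <- c(dose_dur, s$doses$duration)
    obs_ptr[i + 1L] <- length(obs_t)
    dose_ptr[i + 1L] <- length(dose_amt)
  }
  list(subs = subs, n = n, obs_t = obs_t, obs_logdv = obs_logdv,
       obs_ptr = obs_ptr, dose_amt = dose_amt, dose_start = dose_start,
       dose_dur = dose_dur, dose_ptr = dose_ptr)
}

# Typical individual parameter matrix (n x 12): covariate effects and the
# dose-cohort V1 adjustment applied, random effects not.
build_pmat <- function(ld, p, terms) {
  n <- ld$n
  pm <- matrix(0, n, length(.struct_names),
               dimnames = list(NULL, .struct_names))
  for (i in seq_len(n)) {
    s <- ld$subs[[i]]
    pi <- params_for_dose(p, s$dose)
    if (length(terms)) {
      for (nm in unique(vapply(terms, `[[`, "", "param"))) {
        pi[[nm]] <- pi[[nm]] * cov_multiplier(terms, nm, s$covariates)
      }
    }
    pm[i, ] <- unlist(pi[.struct_names], use.names = FALSE)
  }
  pm
}

# Marginal -2 log likelihood given a flattened dataset; dispatches between
# the Laplace path (eta-bearing parameters with positive omega) and the
# degenerate no-random-effects path.
marginal_from_arrays <- function(ld, p, terms, eta_init = NULL, warm = FALSE,
                                 rtol = 1e-6, atol = 1e-9,
                                 pred_floor = 1e-12, fixed_grid = 0,
                                 exact_hessian = FALSE) {
  pm <- build_pmat(ld, p, terms)
  omegas <- c(Rtotp = p$omega_Rtotp, kout = p$omega_kout)
  active <- omegas > 0
  if (!any(active)) {
    tot <- 0
    for (i in seq_len(ld$n)) {
      io <- (ld$obs_ptr[i] + 1L):ld$obs_ptr[i + 1L]
      if (ld$obs_ptr[i + 1L] == ld$obs_ptr[i]) next
      id <- (ld$dose_ptr[i] + 1L):ld$dose_ptr[i + 1L]
      tot <- tot + .tmdd_subject_m2ll_cpp(pm[i, ], p$sigma_log,
                                          ld$obs_t[io], ld$obs_logdv[io],
                                          ld$dose_amt[id], ld$dose_start[id],
                                          ld$dose_dur[id], rtol, atol,
                                          pred_floor, fixed_grid)
    }
    return(list(m2ll = tot, eta = matrix(0, ld$n, 2L), conv = rep(TRUE, ld$n),
                indiv = NULL))
  }
  eta_cols <- c(Rtotp = which(.struct_names == "Rtotp"),
                kout = which(.struct_names == "kout"))[active]
  q <- sum(active)
  omega <- diag(omegas[active]^2, q)
  if (is.null(eta_init)) eta_init <- matrix(0, ld$n, q)
  res <- .tmdd_marginal_cpp(pm, p$sigma_log, omega,
                            as.integer(eta_cols - 1L),
                            ld$obs_t, ld$obs_logdv, as.integer(ld$obs_ptr),
                            ld$dose_amt, ld$dose_start, ld$dose_dur,
                            as.integer(ld$dose_ptr),
                            eta_init, warm, rtol, atol, pred_floor,
                            fixed_grid, exact_hessian)
  eta_full <- matrix(0, ld$n, 2L,
                     dimnames = list(NULL, c("eta_Rtotp", "eta_kout")))
  eta_full[, which(active)] <- res$eta
  list(m2ll = res$m2ll, eta = eta_full, eta_active = res$eta,
       conv = res$conv, indiv = res$indiv, hess = res$hess, active = active)
}

#' Individual -2 log-likelihood
#'
#' The contribution of one subject's observations at fully specified
#' individual parameters, under the additive residual model on natural-log
#' concentration: `sum(log(2 pi sigma^2) + (log y - log C_pred)^2 / sigma^2)`
#' with `C_pred` the model's total concentration at the observation times.
#'
#' @param subject one element of `subject_records(data)`, or a list with
#'   `obs` (data frame time/conc) and `doses` (amount/start/duration).
#' @param p_ind individual `nimo_params` (IIV already applied); its
#'   `sigma_log` is the residual SD.
#' @param pred_floor floor applied to predicted concentrations before taking
#'   logs (underflow protection); a warning is raised when it engages.
#' @param rtol,atol solver tolerances.
#' @return -2 log-likelihood value (scalar).
#' @export
individual_neg2ll <- function(subject, p_ind, pred_floor = 1e-12,
                              rtol = 1e-8, atol = 1e-10) {
  validate_params(p_ind)
  obs <- subject$obs
  if (nrow(obs) == 0L) return(0)
  if (any(!is.finite(obs$conc)) || any(obs$conc <= 0)) {
    stop("observed concentrations must be strictly positive")
  }
  st <- .tmdd_solve_cpp(param_vector(p_ind), subject$doses$amount,
                        subject$doses$start, subject$doses$duration,
                        obs$time, rtol, atol)
  pred <- total_concentration(st[, 1L], p_ind)
  if (any(pred <= pred_floor)) {
    warning("predicted concentrations at or below the floor (",
            pred_floor, " mg/L); flooring")
    pred <- pmax(pred, pred_floor)
  }
  s2 <- p_ind$sigma_log^2
  sum(log(2 * pi * s2) + (log(obs$conc) - log(pred))^2 / s2)
}

#' Marginal -2 log-likelihood of the population model
#'
#' Integrates the random effects out of the likelihood by the Laplace
#' approximation: for each subject the joint -2 log-likelihood is minimised
#' over `eta`, and the curvature at the mode supplies the Gaussian integral
#' correction. Deterministic given data and parameters. With all omegas
#' zero it reduces exactly to the sum of individual contributions at the
#' typical parameters.
#'
#' @param data a `nimo_trial` dataset.
#' @param p a `nimo_params` object (typical values, omegas, residual SD).
#' @param covariate_model optional list of [covariate_term()] effects.
#' @param rtol,atol solver tolerances used inside the likelihood.
#' @param fixed_grid 0 (default) for adaptive error control; a positive
#'   refinement factor switches to the schedule-determined fixed grid the
#'   fitting path uses.
#' @param hessian curvature used in the Laplace correction: the exact
#'   finite-difference Hessian of the joint objective (default) or its
#'   Gauss-Newton approximation ("gn", what [nimo_fit()] uses).
#' @return -2 log marginal likelihood (scalar).
#' @export
marginal_neg2ll <- function(data, p, covariate_model = list(),
                            rtol = 1e-8, atol = 1e-11, fixed_grid = 0,
                            hessian = c("exact", "gn")) {
  validate_params(p)
  hessian <- match.arg(hessian)
  ld <- build_likelihood_data(data)
  terms <- resolve_centers(covariate_model, data)
  marginal_from_arrays(ld, p, terms, rtol = rtol, atol = atol,
                       fixed_grid = fixed_grid,
                       exact_hessian = hessian == "exact")$m2ll
}

#' Fit the population TMDD model
#'
#' Maximum (Laplace-approximated) marginal likelihood estimation of the
#' population model from a trial dataset. Optimisation runs on
#' log-transformed parameters (logit for the bounded 50 mg V1 fraction):
#' an optional Nelder-Mead bracketing phase followed by BFGS with wide-step
#' central-difference gradients. The per-subject random-effect modes are
#' advanced only when the objective improves, so each likelihood evaluation
#' starts its inner search from the best solution found so far.
#'
#' @param data a `nimo_trial` dataset (from [generate_trial()] or
#'   [read_dataset()]).
#' @param init initial `nimo_params`; defaults to the published estimates.
#' @param fix names of parameters to hold fixed at their `init` values.
#'   The default keeps `Kss`, `kint`, `Rtot` and `gamma` fixed.
#' @param covariate_model list of [covariate_term()] objects whose `theta`s
#'   are estimated alongside the population parameters.
#' @param control list: `simplex_maxit` (Nelder-Mead bracketing evaluations,
#'   default 400; 0 skips the phase, appropriate when `init` is already
#'   close), `bfgs_maxit` (gradient-phase iterations, default 60),
#'   `rel_tol` (default 1e-9), `grad_h` (outer finite-difference step,
#'   default 1e-4), `rtol`/`atol` (ODE tolerances, defaults 1e-8/1e-11),
#'   `fixed_grid` (schedule-determined likelihood integration grid
#'   refinement, default 1; 0 switches to adaptive error control),
#'   `trace` (print progress).
#' @return An object of class `nimo_fit` with components `estimates`
#'   (a `nimo_params`), `ofv`, `ebe` (empirical Bayes eta matrix),
#'   `eta_shrinkage`, `eps_shrinkage`, `convergence`, `fixed_mask`,
#'   `covariate_model`, and bookkeeping (data hash, counts, call).
#' @seealso [compare_models()], [scm()], [nimo_bootstrap()], [pc_vpc()]
#' @export
nimo_fit <- function(data, init = nimo_params(),
                     fix = c("Kss", "kint", "Rtot", "gamma"),
                     covariate_model = list(), control = list()) {
  validate_params(init)
  ctl <- modifyList(list(simplex_maxit = 400L, bfgs_maxit = 60L,
                         rel_tol = 1e-9, grad_h = 1e-4,
                         grad_method = "forward", rtol = 1e-8,
                         atol = 1e-11, fixed_grid = 1, trace = FALSE,
                         pred_floor = 1e-12),
                    control)
  bad <- setdiff(fix, .all_par_names)
  if (length(bad)) stop("unknown parameter(s) in 'fix': ",
                        paste(bad, collapse = ", "))
  free <- setdiff(.free_default, fix)
  if (!length(free) && !length(covariate_model)) {
    stop("no free parameters to estimate")
  }
  mode <- init$v1_dose50_mode
  terms <- resolve_centers(covariate_model, data)
  nterms <- length(terms)

  ld <- build_likelihood_data(data)
  nobs_tot <- length(ld$obs_t)

  # Zero-variance components cannot be estimated on the log scale; they must
  # be fixed.
  for (nm in c("omega_Rtotp", "omega_kout", "sigma_log")) {
    if (nm %in% free && init[[nm]] <= 0) {
      stop("'", nm, "' is zero at init; fix it or give a positive start")
    }
  }

  t0 <- vapply(free, function(nm) par_transform(nm, init[[nm]], mode),
               numeric(1))
  if (nterms) {
    tcov0 <- vapply(terms, function(tm) {
      if (tm$type == "fractional") log1p(tm$theta) else tm$theta
    }, numeric(1))
    names(tcov0) <- paste0("beta_", vapply(terms, `[[`, "", "param"), "_",
                           vapply(terms, `[[`, "", "cov"))
    t0 <- c(t0, tcov0)
  }

  state <- new.env(parent = emptyenv())
  state$eta <- NULL
  state$best <- Inf
  state$neval <- 0L

  unpack_theta <- function(tvec) {
    p <- init
    for (j in seq_along(free)) {
      p[[free[j]]] <- par_untransform(free[j], tvec[[j]], mode)
    }
    tms <- terms
    if (nterms) {
      for (k in seq_len(nterms)) {
        tv <- tvec[[length(free) + k]]
        tms[[k]]$theta <- if (tms[[k]]$type == "fractional") {
          expm1(tv)
        } else {
          tv
        }
      }
    }
    list(p = p, terms = tms)
  }

  objective <- function(tvec) {
    pt <- unpack_theta(tvec)
    res <- tryCatch(
      marginal_from_arrays(ld, pt$p, pt$terms,
                           eta_init = state$eta, warm = !is.null(state$eta),
                           rtol = ctl$rtol, atol = ctl$atol,
                           pred_floor = ctl$pred_floor,
                           fixed_grid = ctl$fixed_grid),
      error = function(e) NULL)
    state$neval <- state$neval + 1L
    if (is.null(res) || !is.finite(res$m2ll)) return(1e10)
    # The warm-start eta matrix is only advanced when the objective improves:
    # exploratory side evaluations (simplex reflections, finite-difference
    # steps) must not poison the inner starting points, or the objective
    # becomes history-dependent.
    if (!is.null(res$eta_active) && res$m2ll < state$best) {
      state$eta <- res$eta_active
      state$best <- res$m2ll
    }
    if (isTRUE(ctl$trace)) {
      cat(sprintf("eval %4d  OFV %.4f\n", state$neval, res$m2ll))
    }
    res$m2ll
  }

  # Two-phase outer optimisation.  A simplex pass first brackets the optimum
  # (it tolerates the small solver-tolerance-level jitter of the Laplace
  # objective), then BFGS with wide-step central-difference gradients
  # sharpens it; tiny-step internal finite differences would sit below the
  # jitter floor.
  gradient <- function(tvec) {
    g <- numeric(length(tvec))
    if (identical(ctl$grad_method, "forward")) {
      f0 <- objective(tvec)
      for (j in seq_along(tvec)) {
        h <- ctl$grad_h * (1 + abs(tvec[[j]]))
        up <- tvec
        up[[j]] <- tvec[[j]] + h
        g[j] <- (objective(up) - f0) / h
      }
    } else {
      for (j in seq_along(tvec)) {
        h <- ctl$grad_h * (1 + abs(tvec[[j]]))
        up <- dn <- tvec
        up[[j]] <- tvec[[j]] + h
        dn[[j]] <- tvec[[j]] - h
        g[j] <- (objective(up) - objective(dn)) / (2 * h)
      }
    }
    g
  }
  par1 <- t0
  if (ctl$simplex_maxit > 0L && length(t0) > 1L) {
    opt1 <- optim(t0, objective, method = "Nelder-Mead",
                  control = list(maxit = ctl$simplex_maxit,
                                 reltol = ctl$rel_tol))
    par1 <- opt1$par
  }
  opt <- optim(par1, objective, gr = gradient, method = "BFGS",
               control = list(maxit = ctl$bfgs_maxit, reltol = ctl$rel_tol))
  opt <- list(par = opt$par, objective = opt$value,
              convergence = opt$convergence,
              message = if (opt$convergence == 0) "converged"
                        else paste0("optim code ", opt$convergence),
              iterations = opt$counts[["function"]])

  pt <- unpack_theta(opt$par)
  est <- pt$p
  final <- marginal_from_arrays(ld, est, pt$terms, eta_init = state$eta,
                                warm = !is.null(state$eta),
                                rtol = ctl$rtol, atol = ctl$atol,
                                pred_floor = ctl$pred_floor,
                                fixed_grid = ctl$fixed_grid)

  ebe <- final$eta
  rownames(ebe) <- vapply(ld$subs, function(s) as.character(s$id),
                          character(1))
  omegas <- c(eta_Rtotp = est$omega_Rtotp, eta_kout = est$omega_kout)
  eta_shr <- ifelse(omegas > 0,
                    100 * (1 - apply(ebe, 2L, sd) / omegas), NA_real_)
  names(eta_shr) <- names(omegas)

  iwres <- gof_iwres(ld, est, pt$terms, ebe, ctl)
  eps_shr <- 100 * (1 - sd(iwres))

  fit <- structure(list(
    estimates = est,
    covariate_model = pt$terms,
    ofv = opt$objective,
    aic = opt$objective + 2 * length(opt$par),
    n_params = length(opt$par),
    ebe = ebe,
    eta_shrinkage = eta_shr,
    eps_shrinkage = eps_shr,
    convergence = list(status = opt$convergence, message = opt$message,
                       iterations = opt$iterations,
                       evaluations = state$neval),
    fixed_mask = fix,
    free = free,
    init = init,
    data_hash = data_hash(data),
    n_subjects = ld$n,
    n_obs = nobs_tot,
    control = ctl,
    call = match.call()
  ), class = "nimo_fit")
  fit
}

# IWRES at the empirical Bayes estimates for a flattened dataset.
gof_iwres <- function(ld, p, terms, ebe, ctl) {
  pm <- build_pmat(ld, p, terms)
  iw <- numeric(0)
  for (i in seq_len(ld$n)) {
    if (ld$obs_ptr[i + 1L] == ld$obs_ptr[i]) next
    io <- (ld$obs_ptr[i] + 1L):ld$obs_ptr[i + 1L]
    id <- (ld$dose_ptr[i] + 1L):ld$dose_ptr[i + 1L]
    pv <- pm[i, ]
    pv["Rtotp"] <- pv["Rtotp"] * exp(ebe[i, 1L])
    pv["kout"] <- pv["kout"] * exp(ebe[i, 2L])
    st <- .tmdd_solve_cpp(pv, ld$dose_amt[id], ld$dose_start[id],
                          ld$dose_dur[id], ld$obs_t[io], ctl$rtol, ctl$atol)
    C1 <- st[, 1L] / pv["V1"]
    pred <- pmax(C1 + pv["Rtot"] * C1 / (pv["Kss"] + C1), ctl$pred_floor)
    iw <- c(iw, (ld$obs_logdv[io] - log(pred)) / p$sigma_log)
  }
  iw
}

#' @export
print.nimo_fit <- function(x, ...) {
  cat("Population QSS TMDD model fit (Laplace)\n")
  cat(sprintf("  %d subjects, %d observations; OFV = %.3f\n",
              x$n_subjects, x$n_obs, x$ofv))
  cat(sprintf("  convergence status %d (%s) after %d iterations\n",
              x$convergence$status, x$convergence$message,
              x$convergence$iterations))
  cat("  estimates:\n")
  print(coef(x))
  invisible(x)
}

#' @export
coef.nimo_fit <- function(object, ...) {
  est <- vapply(object$free, function(nm) object$estimates[[nm]], numeric(1))
  if (length(object$covariate_model)) {
    bt <- vapply(object$covariate_model, `[[`, numeric(1), "theta")
    names(bt) <- paste0("beta_",
                        vapply(object$covariate_model, `[[`, "", "param"),
                        "_", vapply(object$covariate_model, `[[`, "", "cov"))
    est <- c(est, bt)
  }
  est
}

#' @export
logLik.nimo_fit <- function(object, ...) {
  structure(-object$ofv / 2, df = object$n_params, nobs = object$n_obs,
            class = "logLik")
}

#' @export
summary.nimo_fit <- function(object, ...) {
  out <- list(
    coef = coef(object),
    ofv = object$ofv, aic = object$aic,
    eta_shrinkage = object$eta_shrinkage,
    eps_shrinkage = object$eps_shrinkage,
    convergence = object$convergence,
    fixed = object$fixed_mask,
    n_subjects = object$n_subjects, n_obs = object$n_obs
  )
  class(out) <- "summary.nimo_fit"
  out
}

#' @export
print.summary.nimo_fit <- function(x, ...) {
  cat("Population QSS TMDD model fit\n")
  cat(sprintf("  OFV %.3f | AIC %.3f | %d subjects, %d observations\n",
              x$ofv, x$aic, x$n_subjects, x$n_obs))
  cat("  Estimates:\n")
  print(x$coef)
  cat("  Fixed:", paste(x$fixed, collapse = ", "), "\n")
  cat(sprintf("  Eta-shrinkage [%%]: Rtotp %.1f, kout %.1f | Eps-shrinkage [%%]: %.1f\n",
              x$eta_shrinkage[1L], x$eta_shrinkage[2L], x$eps_shrinkage))
  invisible(x)
}

#' Model predictions for a fitted population model
#'
#' @param object a `nimo_fit`.
#' @param newdata dataset to predict for; defaults to requiring the original
#'   data (predictions need the dosing/observation design, which the fit does
#'   not store).
#' @param type "pred" for typical-subject (population) predictions,
#'   "ipred" for individual predictions at the empirical Bayes estimates
#'   (only valid for the fitted dataset).
#' @param ... unused.
#' @return Data frame ID, TIME, DV, prediction (total concentration, mg/L).
#' @export
predict.nimo_fit <- function(object, newdata, type = c("ipred", "pred"),
                             ...) {
  type <- match.arg(type)
  ld <- build_likelihood_data(newdata)
  if (type == "ipred" && data_hash(newdata) != object$data_hash) {
    stop("'ipred' requires the dataset the model was fitted to")
  }
  pm <- build_pmat(ld, object$estimates, object$covariate_model)
  out <- vector("list", ld$n)
  for (i in seq_len(ld$n)) {
    s <- ld$subs[[i]]
    if (nrow(s$obs) == 0L) next
    pv <- pm[i, ]
    if (type == "ipred") {
      pv["Rtotp"] <- pv["Rtotp"] * exp(object$ebe[i, 1L])
      pv["kout"] <- pv["kout"] * exp(object$ebe[i, 2L])
    }
    st <- .tmdd_solve_cpp(pv, s$doses$amount, s$doses$start,
                          s$doses$duration, s$obs$time, 1e-8, 1e-10)
    C1 <- st[, 1L] / pv["V1"]
    out[[i]] <- data.frame(ID = s$id, TIME = s$obs$time, DV = s$obs$conc,
                           pred = C1 + pv["Rtot"] * C1 / (pv["Kss"] + C1))
  }
  res <- do.call(rbind, out)
  names(res)[4L] <- type
  rownames(res) <- NULL
  res
}

#' @export
residuals.nimo_fit <- function(object, data, ...) {
  gof_residuals(data, object)
}

#' Simulate replicate trials from a fitted model
#'
#' Draws new random effects and residuals on the design of `data` (same
#' subjects, dosing, sampling times and covariates).
#'
#' @param object a `nimo_fit`.
#' @param nsim number of replicate datasets.
#' @param seed RNG seed.
#' @param data the template dataset (defaults to requiring one explicitly).
#' @param ... unused.
#' @return List of `nimo_trial` datasets.
#' @export
simulate.nimo_fit <- function(object, nsim = 1, seed = NULL, data, ...) {
  local_seed(seed)
  lapply(seq_len(nsim), function(i) {
    simulate_from_design(data, object$estimates, object$covariate_model)
  })
}

#' @export
plot.nimo_fit <- function(x, data, ...) {
  res <- gof_residuals(data, x)
  graphics::par(mfrow = c(2, 2))
  on.exit(graphics::par(mfrow = c(1, 1)))
  graphics::plot(res$PRED, res$DV, log = "xy", xlab = "PRED (mg/L)",
                 ylab = "observed (mg/L)", ...)
  graphics::abline(0, 1, lty = 2)
  graphics::plot(res$IPRED, res$DV, log = "xy", xlab = "IPRED (mg/L)",
                 ylab = "observed (mg/L)", ...)
  graphics::abline(0, 1, lty = 2)
  graphics::plot(res$TIME, res$IWRES, xlab = "time (h)", ylab = "IWRES", ...)
  graphics::abline(h = 0, lty = 2)
  graphics::plot(res$TIME, res$CWRES, xlab = "time (h)", ylab = "CWRES", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

# Simulate one replicate dataset on the design of `data` under parameters
# `p` (typical + omegas + sigma) and an optional covariate model.
simulate_from_design <- function(data, p, covariate_model = list()) {
  ld <- build_likelihood_data(data)
  terms <- resolve_centers(covariate_model, data)
  pm <- build_pmat(ld, p, terms)
  out <- as.data.frame(data)
  for (i in seq_len(ld$n)) {
    s <- ld$subs[[i]]
    if (nrow(s$obs) == 0L) next
    pv <- pm[i, ]
    pv["Rtotp"] <- pv["Rtotp"] * exp(rnorm(1L, 0, p$omega_Rtotp))
    pv["kout"] <- pv["kout"] * exp(rnorm(1L, 0, p$omega_kout))
    st <- .tmdd_solve_cpp(pv, s$doses$amount, s$doses$start,
                          s$doses$duration, s$obs$time, 1e-8, 1e-10)
    C1 <- st[, 1L] / pv["V1"]
    pred <- C1 + pv["Rtot"] * C1 / (pv["Kss"] + C1)
    dv <- exp(log(pmax(pred, 1e-12)) +
                rnorm(length(pred), 0, p$sigma_log))
    rows <- which(out$ID == s$id & out$EVID == 0L & out$MDV == 0L)
    out$DV[rows] <- dv
  }
  class(out) <- c("nimo_trial", "data.frame")
  out
}

#' Compare two fitted models
#'
#' Nested models are compared by the drop in objective function value
#' against a chi-square criterion (7.879 per degree of freedom at the
#' default alpha = 0.005); non-nested models by AIC.
#'
#' @param fitA,fitB `nimo_fit` objects fitted to the same dataset.
#' @param nested are the models nested? If so `fitB` is taken as the larger
#'   model when it has more estimated parameters.
#' @param df degrees-of-freedom difference for the nested test; defaults to
#'   the difference in parameter counts.
#' @param alpha significance level of the nested test.
#' @return List with `preferred` ("A" or "B"), `delta_ofv` (nested) or AIC
#'   values, and the decision rule applied.
#' @export
compare_models <- function(fitA, fitB, nested = TRUE, df = NULL,
                           alpha = 0.005) {
  stopifnot(inherits(fitA, "nimo_fit"), inherits(fitB, "nimo_fit"))
  if (!identical(fitA$data_hash, fitB$data_hash)) {
    stop("models were fitted to different datasets; comparison is invalid")
  }
  if (nested) {
    if (fitA$n_params == fitB$n_params) {
      # Equal complexity: tie on equal OFV, otherwise prefer the lower OFV.
      pref <- if (fitA$ofv == fitB$ofv) "tie" else
        if (fitA$ofv < fitB$ofv) "A" else "B"
      return(list(preferred = pref, rule = "nested",
                  delta_ofv = abs(fitA$ofv - fitB$ofv), threshold = 0,
                  accept_larger = FALSE))
    }
    larger <- if (fitA$n_params > fitB$n_params) "A" else "B"
    smaller <- setdiff(c("A", "B"), larger)
    fl <- if (larger == "A") fitA else fitB
    fs <- if (smaller == "A") fitA else fitB
    if (is.null(df)) df <- fl$n_params - fs$n_params
    delta <- fs$ofv - fl$ofv
    thr <- qchisq(1 - alpha, df)
    accept <- is.finite(delta) && delta >= thr
    list(preferred = if (accept) larger else smaller, rule = "nested",
         delta_ofv = delta, df = df, threshold = thr,
         accept_larger = accept)
  } else {
    aicA <- fitA$ofv + 2 * fitA$n_params
    aicB <- fitB$ofv + 2 * fitB$n_params
    pref <- if (aicA < aicB) {
      "A"
    } else if (aicB < aicA) {
      "B"
    } else if (fitA$n_params < fitB$n_params) {
      "A"
    } else if (fitB$n_params < fitA$n_params) {
      "B"
    } else {
      "tie"
    }
    list(preferred = pref, rule = "aic", aic = c(A = aicA, B = aicB))
  }
}
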