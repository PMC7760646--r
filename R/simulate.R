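#' Intravenous infusion event
#'
#' @param amount dose amount (mg).
#' @param start infusion start time (h).
#' @param duration infusion duration (h); the trial used 30-minute infusions.
#' @return A one-row data frame with columns `amount`, `start`, `duration`.
#' @export
dose_event <- function(amount, start = 0, duration = 0.5) {
  if (any(!is.finite(amount)) || any(amount <= 0)) {
    stop("'amount' must be strictly positive")
  }
  if (any(!is.finite(duration)) || any(duration <= 0)) {
    stop("'duration' must be strictly positive")
  }
  if (any(!is.finite(start)) || any(start < 0)) {
    stop("'start' must be non-negative")
  }
  data.frame(amount = amount, start = start, duration = duration)
}

#' Simulate a concentration-time profile
#'
#' Integrates the QSS TMDD system from the rest state (no drug, mediator at
#' its pre-dose steady state) over a set of infusion events, with integration
#' restarted at every infusion start/end so the input discontinuities are
#' never smoothed across.
#'
#' @param p a `nimo_params` object. The cohort V1 adjustment is *not* applied
#'   here; use [params_for_dose()] or [dose_sweep()] when simulating the
#'   50 mg arm of the trial.
#' @param doses a data frame of infusion events as built by [dose_event()]
#'   (rows may be concatenated with `rbind` for multiple-dose regimens).
#' @param times output time grid (h), sorted, non-negative.
#' @param rtol,atol relative/absolute solver tolerances.
#' @return A data frame of class `nimo_sim` with columns `time`,
#'   `free_central_conc` (mg/L), `total_central_conc` (mg/L),
#'   `peripheral_conc` (mg/L), `mediator`; the parameters and dose events are
#'   attached as attributes.
#' @examples
#' p <- nimo_params()
#' sim <- nimo_simulate(p, dose_event(100), times = seq(0, 1000, by = 0.5))
#' time_above_threshold(sim, p$Kss)
#' @export
nimo_simulate <- function(p, doses, times = seq(0, 1000, by = 0.5),
                          rtol = 1e-8, atol = 1e-10) {
  validate_params(p)
  if (!is.data.frame(doses) ||
      !all(c("amount", "start", "duration") %in% names(doses))) {
    stop("'doses' must be a data frame with amount/start/duration columns")
  }
  if (is.unsorted(times) || any(times < 0) || any(!is.finite(times))) {
    stop("'times' must be sorted, finite and non-negative")
  }
  if (rtol <= 0 || atol <= 0) stop("solver tolerances must be positive")
  st <- .tmdd_solve_cpp(param_vector(p), doses$amount, doses$start,
                        doses$duration, as.numeric(times), rtol, atol)
  C1 <- st[, 1L] / p$V1
  out <- data.frame(
    time = as.numeric(times),
    free_central_conc = C1,
    total_central_conc = C1 + p$Rtot * C1 / (p$Kss + C1),
    peripheral_conc = st[, 2L] / p$V2,
    mediator = st[, 3L]
  )
  attr(out, "params") <- p
  attr(out, "doses") <- doses
  class(out) <- c("nimo_sim", "data.frame")
  out
}

#' Time a concentration profile spends above a threshold
#'
#' Total duration during which the chosen concentration series exceeds the
#' threshold, with crossing times obtained by linear interpolation between
#' grid points.
#'
#' @param sim a `nimo_sim` object (or any data frame with a `time` column and
#'   the requested series).
#' @param threshold concentration threshold (mg/L), strictly positive.
#' @param which which series to assess: `"free"` or `"total"` central
#'   concentration.
#' @return Duration in hours.
#' @export
time_above_threshold <- function(sim, threshold, which = c("free", "total")) {
  which <- match.arg(which)
  if (!is.finite(threshold) || threshold <= 0) {
    stop("'threshold' must be strictly positive")
  }
  col <- if (which == "free") "free_central_conc" else "total_central_conc"
  if (!is.data.frame(sim) || nrow(sim) == 0L || !col %in% names(sim)) {
    stop("'sim' must be a non-empty simulation result with a '", col,
         "' column")
  }
  t <- sim$time
  y <- sim[[col]]
  if (length(t) < 2L) stop("'sim' must contain at least two time points")
  dt <- diff(t)
  y1 <- y[-length(y)]
  y2 <- y[-1L]
  frac <- numeric(length(dt))
  both <- y1 > threshold & y2 > threshold
  down <- y1 > threshold & y2 <= threshold
  up <- y1 <= threshold & y2 > threshold
  frac[both] <- 1
  frac[down] <- (y1[down] - threshold) / (y1[down] - y2[down])
  frac[up] <- (y2[up] - threshold) / (y2[up] - y1[up])
  sum(dt * frac)
}

# Trapezoidal area under a sampled curve.
trapz <- function(t, y) {
  sum(diff(t) * (head(y, -1L) + y[-1L]) / 2)
}

#' Deterministic dose-selection sweep
#'
#' Simulates single 30-minute infusions of each dose in a typical subject and
#' derives the exposure metrics used for dose selection: Cmax, trapezoidal
#' AUC over the horizon, and time above the QSS binding constant. The cohort
#' V1 adjustment is applied to the 50 mg arm only (its direction is set by
#' `p$v1_dose50_mode`).
#'
#' @param p a `nimo_params` object.
#' @param doses dose amounts in mg.
#' @param horizon simulation horizon (h).
#' @param dt output grid step (h).
#' @param threshold threshold for the time-above metric; defaults to `p$Kss`.
#' @param infusion_duration infusion length (h).
#' @param rtol,atol solver tolerances.
#' @return A list of class `nimo_sweep` with elements `profiles` (named list
#'   of `nimo_sim`), `metrics` (data frame: dose, cmax_free, cmax_total,
#'   auc_total, time_above), and `pct_increase` (percent increase of the
#'   time-above metric between successive doses).
#' @export
dose_sweep <- function(p, doses = c(50, 100, 200, 400, 800, 1200),
                       horizon = 1000, dt = 0.5, threshold = p$Kss,
                       infusion_duration = 0.5, rtol = 1e-8, atol = 1e-10) {
  validate_params(p)
  doses <- sort(unique(doses))
  times <- seq(0, horizon, by = dt)
  profiles <- vector("list", length(doses))
  names(profiles) <- as.character(doses)
  metrics <- data.frame(dose = doses, cmax_free = NA_real_,
                        cmax_total = NA_real_, auc_total = NA_real_,
                        time_above = NA_real_)
  for (i in seq_along(doses)) {
    d <- doses[i]
    pd <- params_for_dose(p, d)
    sim <- tryCatch(
      nimo_simulate(pd, dose_event(d, duration = infusion_duration), times,
                    rtol = rtol, atol = atol),
      error = function(e) stop("integration failed for dose ", d, " mg: ",
                               conditionMessage(e)))
    profiles[[i]] <- sim
    metrics$cmax_free[i] <- max(sim$free_central_conc)
    metrics$cmax_total[i] <- max(sim$total_central_conc)
    metrics$auc_total[i] <- trapz(sim$time, sim$total_central_conc)
    metrics$time_above[i] <- time_above_threshold(sim, threshold, "free")
  }
  pct <- if (length(doses) > 1L) {
    100 * diff(metrics$time_above) / head(metrics$time_above, -1L)
  } else {
    numeric(0)
  }
  names(pct) <- if (length(doses) > 1L) {
    paste(head(doses, -1L), doses[-1L], sep = "->")
  } else {
    character(0)
  }
  structure(list(profiles = profiles, metrics = metrics, pct_increase = pct,
                 threshold = threshold, params = p),
            class = "nimo_sweep")
}

#' @export
print.nimo_sweep <- function(x, ...) {
  cat("Dose-selection sweep (threshold", x$threshold, "mg/L)\n")
  print(x$metrics, row.names = FALSE)
  if (length(x$pct_increase)) {
    cat("Percent increase in time above threshold between successive doses:\n")
    print(round(x$pct_increase, 1))
  }
  invisible(x)
}

#' @export
print.nimo_sim <- function(x, ...) {
  p <- attr(x, "params")
  cat("QSS TMDD simulation:", nrow(x), "time points, ",
      sprintf("t in [%g, %g] h\n", min(x$time), max(x$time)))
  print.data.frame(utils::head(as.data.frame(x), 6), row.names = FALSE)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' @export
plot.nimo_sim <- function(x, log = "y", ...) {
  graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(mfrow = c(1, 1)))
  pos <- x$total_central_conc > 0
  graphics::plot(x$time[pos], x$total_central_conc[pos], type = "l",
                 log = log, xlab = "time (h)",
                 ylab = "total central conc (mg/L)", ...)
  graphics::plot(x$time, x$mediator, type = "l", xlab = "time (h)",
                 ylab = "mediator", ...)
  invisible(x)
}
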