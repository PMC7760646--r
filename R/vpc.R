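#' Prediction-corrected visual predictive check
#'
#' Simulates replicate trials under the model on the observed design and
#' compares percentiles of prediction-corrected observations with the
#' simulation-based prediction intervals of the same percentiles. The
#' correction is multiplicative on the natural scale (additive on the log
#' scale, matching the residual model): each observation and each simulated
#' value is scaled by `median(PRED in bin) / PRED_ij`, where PRED is the
#' population prediction for that record. Bins default to the nominal
#' sampling times, which in this balanced design puts every observation time
#' in its own bin.
#'
#' @param data a `nimo_trial` dataset.
#' @param p `nimo_params` to simulate under (typically fitted estimates).
#' @param n_sim number of replicate trials (at least 50).
#' @param bins optional numeric vector of bin break points on the time axis;
#'   default uses each nominal time as its own bin. Empty user bins are
#'   merged with their left neighbour with a warning.
#' @param seed RNG seed for the replicates.
#' @param percentiles percentiles summarised within each bin.
#' @param ci width of the simulation interval around each percentile.
#' @param covariate_model optional covariate terms used for the predictions.
#' @return An object of class `nimo_vpc`: a data frame with one row per bin
#'   (bin midpoint, n, observed percentiles, simulation interval bounds for
#'   each percentile), with `n_replicates` attached.
#' @export
pc_vpc <- function(data, p, n_sim = 1000, bins = NULL, seed = NULL,
                   percentiles = c(2.5, 50, 97.5), ci = 0.95,
                   covariate_model = list()) {
  validate_params(p)
  if (n_sim < 50) stop("'n_sim' must be at least 50")
  local_seed(seed)
  ld <- build_likelihood_data(data)
  terms <- resolve_centers(covariate_model, data)

  obs_rows <- which(data$EVID == 0L & data$MDV == 0L)
  tt <- data$TIME[obs_rows]
  dv <- data$DV[obs_rows]

  # Population predictions per observation record, matched by row so that
  # interleaved subject records stay aligned.
  pm <- build_pmat(ld, p, terms)
  pred <- numeric(length(obs_rows))
  ids <- data$ID[obs_rows]
  for (i in seq_len(ld$n)) {
    s <- ld$subs[[i]]
    m <- nrow(s$obs)
    if (m == 0L) next
    st <- .tmdd_solve_cpp(pm[i, ], s$doses$amount, s$doses$start,
                          s$doses$duration, s$obs$time, 1e-8, 1e-10)
    C1 <- st[, 1L] / pm[i, "V1"]
    pred[ids == s$id] <- C1 + pm[i, "Rtot"] * C1 / (pm[i, "Kss"] + C1)
  }

  if (is.null(bins)) {
    bin_id <- match(tt, sort(unique(tt)))
    bin_mid <- sort(unique(tt))
  } else {
    breaks <- sort(unique(bins))
    bin_id <- findInterval(tt, breaks, rightmost.closed = TRUE)
    keep <- sort(unique(bin_id))
    if (length(keep) < length(breaks) - 1L) {
      warning("empty bin(s) merged with their neighbour")
    }
    bin_id <- match(bin_id, keep)
    bin_mid <- vapply(seq_along(keep),
                      function(b) mean(tt[bin_id == b]), numeric(1))
  }
  nb <- length(bin_mid)

  # Prediction correction factor per record.
  med_pred <- vapply(seq_len(nb),
                     function(b) median(pred[bin_id == b]), numeric(1))
  corr <- med_pred[bin_id] / pred

  qs <- percentiles / 100
  obs_pc <- dv * corr
  obs_q <- t(vapply(seq_len(nb), function(b) {
    quantile(obs_pc[bin_id == b], probs = qs, names = FALSE)
  }, numeric(length(qs))))

  sim_q <- array(NA_real_, dim = c(n_sim, nb, length(qs)))
  for (r in seq_len(n_sim)) {
    rep_data <- simulate_from_design(data, p, terms)
    sim_pc <- rep_data$DV[obs_rows] * corr
    for (b in seq_len(nb)) {
      sim_q[r, b, ] <- quantile(sim_pc[bin_id == b], probs = qs,
                                names = FALSE)
    }
  }
  a <- (1 - ci) / 2
  lo <- apply(sim_q, c(2L, 3L), quantile, probs = a, names = FALSE)
  hi <- apply(sim_q, c(2L, 3L), quantile, probs = 1 - a, names = FALSE)
  med <- apply(sim_q, c(2L, 3L), median)

  out <- data.frame(bin_mid = bin_mid,
                    n = vapply(seq_len(nb),
                               function(b) sum(bin_id == b), integer(1)))
  for (j in seq_along(qs)) {
    lab <- formatC(percentiles[j], format = "g")
    out[[paste0("obs_p", lab)]] <- obs_q[, j]
    out[[paste0("sim_p", lab, "_lo")]] <- lo[, j]
    out[[paste0("sim_p", lab, "_med")]] <- med[, j]
    out[[paste0("sim_p", lab, "_hi")]] <- hi[, j]
  }
  attr(out, "n_replicates") <- n_sim
  attr(out, "percentiles") <- percentiles
  attr(out, "ci") <- ci
  class(out) <- c("nimo_vpc", "data.frame")
  out
}

#' Fraction of bins whose observed percentile lies inside its simulation band
#'
#' @param vpc a `nimo_vpc` object.
#' @param percentile which percentile to check (default the median).
#' @return Fraction in [0, 1].
#' @export
vpc_coverage <- function(vpc, percentile = 50) {
  lab <- formatC(percentile, format = "g")
  obs <- vpc[[paste0("obs_p", lab)]]
  lo <- vpc[[paste0("sim_p", lab, "_lo")]]
  hi <- vpc[[paste0("sim_p", lab, "_hi")]]
  if (is.null(obs)) stop("percentile ", percentile, " not in VPC result")
  mean(obs >= lo & obs <= hi)
}

#' @export
print.nimo_vpc <- function(x, ...) {
  cat(sprintf("pc-VPC: %d bins, %d replicates; median-band coverage %.0f%%\n",
              nrow(x), attr(x, "n_replicates"), 100 * vpc_coverage(x)))
  print.data.frame(utils::head(as.data.frame(x), 4), row.names = FALSE,
                   digits = 3)
  if (nrow(x) > 4) cat("...\n")
  invisible(x)
}

#' @export
plot.nimo_vpc <- function(x, log = "y", ...) {
  tt <- x$bin_mid
  ylim <- range(c(x$obs_p2.5, x$obs_p97.5, x$sim_p2.5_lo, x$sim_p97.5_hi),
                na.rm = TRUE)
  graphics::plot(tt, x$obs_p50, type = "n", log = log, ylim = ylim,
                 xlab = "time (h)", ylab = "prediction-corrected conc (mg/L)",
                 ...)
  shade <- function(lo, hi, col) {
    graphics::polygon(c(tt, rev(tt)), c(lo, rev(hi)), col = col, border = NA)
  }
  shade(x$sim_p2.5_lo, x$sim_p2.5_hi, grDevices::adjustcolor("steelblue", 0.3))
  shade(x$sim_p50_lo, x$sim_p50_hi, grDevices::adjustcolor("firebrick", 0.3))
  shade(x$sim_p97.5_lo, x$sim_p97.5_hi,
        grDevices::adjustcolor("steelblue", 0.3))
  graphics::lines(tt, x$obs_p50, lwd = 2)
  graphics::lines(tt, x$obs_p2.5, lty = 2)
  graphics::lines(tt, x$obs_p97.5, lty = 2)
  invisible(x)
}
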