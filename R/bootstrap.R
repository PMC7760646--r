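#' Nonparametric bootstrap of the population fit
#'
#' Resamples subjects with replacement to the original size, refits the
#' model on each replicate (starting from `init`, typically the original
#' point estimates), and tabulates the median and the 2.5th/97.5th
#' percentiles of every estimated parameter. Replicates whose fit errors
#' out or fails to converge are counted and excluded; the result is flagged
#' unreliable when more than 20% of replicates fail.
#'
#' @param data a `nimo_trial` dataset.
#' @param init starting `nimo_params` for every replicate fit.
#' @param n_resamples number of bootstrap replicates (at least 2).
#' @param seed RNG seed governing the resampling.
#' @param fix parameters held fixed (as in [nimo_fit()]).
#' @param covariate_model covariate terms carried into each fit.
#' @param control fit control list; bootstrap replicates default to a
#'   slightly looser outer tolerance than a primary fit.
#' @param .resample_matrix optional integer matrix (n_resamples x n_subjects)
#'   of prespecified subject draws, used for deterministic testing.
#' @return An object of class `nimo_boot`: `estimates` (replicate table),
#'   `summary` (median/2.5/97.5 per parameter), `n_resamples`, `n_failed`,
#'   `unreliable`.
#' @export
nimo_bootstrap <- function(data, init = nimo_params(), n_resamples = 500,
                           seed = NULL, fix = c("Kss", "kint", "Rtot",
                                                "gamma"),
                           covariate_model = list(), control = list(),
                           .resample_matrix = NULL) {
  if (n_resamples < 2) stop("'n_resamples' must be at least 2")
  local_seed(seed)
  ctl <- modifyList(list(iter_max = 100L, rel_tol = 1e-7), control)
  ids <- unique(data$ID)
  n <- length(ids)
  if (is.null(.resample_matrix)) {
    .resample_matrix <- matrix(sample.int(n, n * n_resamples, replace = TRUE),
                               nrow = n_resamples)
  }
  stopifnot(ncol(.resample_matrix) == n)

  rows <- vector("list", n_resamples)
  failed <- 0L
  for (r in seq_len(n_resamples)) {
    take <- ids[.resample_matrix[r, ]]
    pieces <- lapply(seq_along(take), function(j) {
      d <- data[data$ID == take[j], , drop = FALSE]
      d$ID <- j
      d
    })
    boot_data <- do.call(rbind, pieces)
    class(boot_data) <- c("nimo_trial", "data.frame")
    fit <- tryCatch(
      nimo_fit(boot_data, init = init, fix = fix,
               covariate_model = covariate_model, control = ctl),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$ofv)) {
      failed <- failed + 1L
      next
    }
    rows[[r]] <- c(coef(fit), ofv = fit$ofv)
  }
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(tab) || nrow(tab) == 0L) {
    stop("all bootstrap replicates failed")
  }
  pars <- setdiff(colnames(tab), "ofv")
  smry <- t(vapply(pars, function(nm) {
    c(median = median(tab[, nm]),
      p2.5 = unname(quantile(tab[, nm], 0.025)),
      p97.5 = unname(quantile(tab[, nm], 0.975)))
  }, numeric(3)))
  structure(list(estimates = as.data.frame(tab), summary = smry,
                 n_resamples = n_resamples, n_failed = failed,
                 unreliable = failed > 0.2 * n_resamples,
                 data_hash = data_hash(data)),
            class = "nimo_boot")
}

#' @export
print.nimo_boot <- function(x, ...) {
  cat(sprintf("Nonparametric bootstrap: %d resamples, %d failed%s\n",
              x$n_resamples, x$n_failed,
              if (x$unreliable) " [UNRELIABLE: >20% failures]" else ""))
  print(round(x$summary, 5))
  invisible(x)
}
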