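#' Covariate effect term
#'
#' Describes one parameter-covariate relationship in the pharmacometric
#' convention: continuous covariates act as power functions centered on a
#' reference value, `P * (cov/center)^theta`; categorical covariates act as
#' fractional shifts, `P * (1 + theta * I(cov != center))`.
#'
#' @param param name of the structural parameter the covariate acts on.
#' @param cov covariate column name (e.g. "WT", "SEX").
#' @param type "power" (continuous) or "fractional" (categorical).
#' @param theta effect size (exponent, or fractional shift > -1).
#' @param center reference value: the centering constant for power terms
#'   (defaults to the data median when applied), or the reference category
#'   for fractional terms (defaults to 1).
#' @return An object of class `nimo_cov_term`.
#' @export
covariate_term <- function(param, cov, type = c("power", "fractional"),
                           theta = 0, center = NULL) {
  type <- match.arg(type)
  if (!param %in% .struct_names) {
    stop("unknown structural parameter '", param, "'")
  }
  if (type == "fractional" && theta <= -1) {
    stop("fractional shift must be greater than -1")
  }
  structure(list(param = param, cov = cov, type = type, theta = theta,
                 center = center), class = "nimo_cov_term")
}

# Resolve missing centers of covariate terms against a dataset (median for
# power terms, reference category 1 for fractional terms).
resolve_centers <- function(terms, data) {
  lapply(terms, function(tm) {
    if (is.null(tm$center)) {
      tm$center <- if (tm$type == "power") {
        stats::median(data[[tm$cov]][data$EVID == 1], na.rm = TRUE)
      } else {
        1
      }
    }
    tm
  })
}

# Multiplier a set of covariate terms applies to one parameter for one
# subject (covs = named list/row of covariate values).
cov_multiplier <- function(terms, param, covs) {
  m <- 1
  for (tm in terms) {
    if (tm$param != param) next
    x <- covs[[tm$cov]]
    m <- m * if (tm$type == "power") {
      (x / tm$center)^tm$theta
    } else {
      1 + tm$theta * as.numeric(x != tm$center)
    }
  }
  m
}

#' Generate a virtual phase-I trial dataset
#'
#' Simulates a complete trial under the model: subjects are assigned to dose
#' cohorts, covariates and random effects are drawn, each subject's
#' concentration profile is solved at the design's sampling times, and
#' observations are produced as `exp(log(C_pred) + eps)` with
#' `eps ~ N(0, sigma_log^2)` applied to the total (free plus bound)
#' concentration. The cohort V1 adjustment applies to the 50 mg arm. The
#' pre-dose sample is kept as a missing-observation record.
#'
#' @param p a `nimo_params` object (typical values, omegas, sigma).
#' @param design a `nimo_design` object.
#' @param seed RNG seed for reproducibility.
#' @param covariate_effects optional list of [covariate_term()] objects
#'   injected into the individual parameters (used to create true-positive
#'   test beds for covariate screening; the final published model has none).
#' @param apply_lloq if `TRUE`, observations below the assay LLOQ are flagged
#'   missing (`MDV = 1`). Off by default: no observation fell below the LLOQ
#'   in the original study.
#' @return A data frame of class `nimo_trial` in NONMEM-style long format
#'   with columns ID, TIME, AMT, RATE, DV, MDV, EVID, DOSE and the covariate
#'   columns. Generating parameters, design, seed and the realized `eta`
#'   matrix are attached as attributes.
#' @examples
#' trial <- generate_trial(nimo_params(), trial_design(), seed = 1)
#' table(trial$DOSE[trial$EVID == 1])
#' @export
generate_trial <- function(p, design = trial_design(), seed = NULL,
                           covariate_effects = list(), apply_lloq = FALSE) {
  validate_params(p)
  stopifnot(inherits(design, "nimo_design"))
  local_seed(seed)

  n <- design$n_per_cohort * length(design$dose_levels)
  dose_by_subj <- rep(design$dose_levels, each = design$n_per_cohort)
  covs <- sample_covariates(n)
  eta <- cbind(eta_Rtotp = rnorm(n, 0, p$omega_Rtotp),
               eta_kout = rnorm(n, 0, p$omega_kout))
  tobs <- design$sampling_times
  eps <- matrix(rnorm(n * length(tobs), 0, p$sigma_log), nrow = n)

  terms <- covariate_effects
  if (length(terms)) {
    terms <- lapply(terms, function(tm) {
      if (is.null(tm$center)) {
        tm$center <- if (tm$type == "power") {
          stats::median(covs[[tm$cov]])
        } else {
          1
        }
      }
      tm
    })
  }

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    d <- dose_by_subj[i]
    pi <- params_for_dose(p, d)
    for (nm in .struct_names) {
      pi[[nm]] <- pi[[nm]] * cov_multiplier(terms, nm, covs[i, ])
    }
    pi$Rtotp <- pi$Rtotp * exp(eta[i, 1L])
    pi$kout <- pi$kout * exp(eta[i, 2L])
    st <- tryCatch(
      .tmdd_solve_cpp(param_vector(pi), d, 0, design$infusion_duration,
                      tobs, 1e-8, 1e-10),
      error = function(e) stop("integration failed for subject ", i,
                               " (dose ", d, " mg): ", conditionMessage(e)))
    C1 <- st[, 1L] / pi$V1
    pred <- C1 + pi$Rtot * C1 / (pi$Kss + C1)
    dv <- exp(log(pred) + eps[i, ])
    mdv <- rep(0L, length(tobs))
    if (apply_lloq) mdv[dv < design$lloq] <- 1L
    cv <- covs[i, , drop = FALSE]
    sub <- data.frame(
      ID = i,
      TIME = c(0, 0, tobs),
      AMT = c(d, NA, rep(NA_real_, length(tobs))),
      RATE = c(d / design$infusion_duration, NA, rep(NA_real_, length(tobs))),
      DV = c(NA, NA, dv),
      MDV = c(1L, 1L, mdv),
      EVID = c(1L, 0L, rep(0L, length(tobs))),
      DOSE = d,
      row.names = NULL
    )
    rows[[i]] <- cbind(sub, cv[rep(1L, nrow(sub)), , drop = FALSE],
                       row.names = NULL)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "params") <- p
  attr(out, "design") <- design
  attr(out, "seed") <- seed
  attr(out, "eta") <- eta
  attr(out, "covariate_effects") <- terms
  class(out) <- c("nimo_trial", "data.frame")
  out
}

#' @export
print.nimo_trial <- function(x, ...) {
  nid <- length(unique(x$ID))
  nobs <- sum(x$EVID == 0 & x$MDV == 0)
  cat(sprintf("Virtual trial dataset: %d subjects, %d observations, doses %s mg\n",
              nid, nobs,
              paste(sort(unique(x$DOSE)), collapse = "/")))
  print.data.frame(utils::head(as.data.frame(x), 5), row.names = FALSE,
                   digits = 4)
  if (nrow(x) > 5) cat("...", nrow(x) - 5, "more rows\n")
  invisible(x)
}

# Split a trial dataset into per-subject records (dosing, observations,
# covariates) for the likelihood machinery.
subject_records <- function(data) {
  if (!all(c("ID", "TIME", "AMT", "RATE", "DV", "MDV", "EVID") %in%
           names(data))) {
    stop("dataset is missing required columns")
  }
  ids <- unique(data$ID)
  lapply(ids, function(id) {
    d <- data[data$ID == id, , drop = FALSE]
    dosing <- d[d$EVID == 1L, , drop = FALSE]
    obs <- d[d$EVID == 0L & d$MDV == 0L, , drop = FALSE]
    covnames <- intersect(c("AGE", "WT", "HT", "BSA", "SCR", "CRCL", "TKV",
                            "TCV", "SEX", "RACE"), names(d))
    list(
      id = id,
      dose = if (nrow(dosing)) dosing$DOSE[1L] else NA_real_,
      doses = data.frame(amount = dosing$AMT, start = dosing$TIME,
                         duration = dosing$AMT / dosing$RATE),
      obs = data.frame(time = obs$TIME, conc = obs$DV),
      covariates = if (length(covnames)) as.list(d[1L, covnames]) else list()
    )
  })
}
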