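#' Phase-I trial design
#'
#' Encodes the dose-escalation design of the single-dose phase-I study the
#' model was developed on: 4 cohorts of 5 subjects at 50/100/200/400 mg, a
#' 30-minute IV infusion, a pre-dose sample and 23 post-dose serum samples
#' between 0.5 and 672 h.
#'
#' @param n_per_cohort subjects per dose cohort.
#' @param dose_levels cohort dose amounts (mg).
#' @param infusion_duration infusion length (h).
#' @param sampling_times post-dose sampling times (h), strictly increasing.
#' @param lloq lower limit of quantification of the assay (mg/L). No
#'   observation in the original study fell below it; it is carried along so
#'   that generated datasets can flag sub-LLOQ values, but it is inert under
#'   the default parameters.
#' @return An object of class `nimo_design`.
#' @export
trial_design <- function(n_per_cohort = 5,
                         dose_levels = c(50, 100, 200, 400),
                         infusion_duration = 0.5,
                         sampling_times = c(0.5, 1, 2, 6, 12, 24, 36, 48, 72,
                                            96, 120, 144, 168, 240, 338, 432,
                                            504, 552, 576, 600, 624, 648, 672),
                         lloq = 7.8e-3) {
  if (any(dose_levels <= 0)) stop("'dose_levels' must be positive")
  if (is.unsorted(sampling_times, strictly = TRUE)) {
    stop("'sampling_times' must be strictly increasing")
  }
  if (any(sampling_times <= 0)) stop("'sampling_times' must be positive")
  structure(list(n_per_cohort = n_per_cohort, dose_levels = dose_levels,
                 infusion_duration = infusion_duration,
                 sampling_times = sampling_times, lloq = lloq),
            class = "nimo_design")
}

#' @export
print.nimo_design <- function(x, ...) {
  cat(sprintf(
    "Trial design: %d cohorts x %d subjects, doses %s mg, %g h infusion\n",
    length(x$dose_levels), x$n_per_cohort,
    paste(x$dose_levels, collapse = "/"), x$infusion_duration))
  cat(sprintf("  %d post-dose samples in [%g, %g] h; LLOQ %g mg/L\n",
              length(x$sampling_times), min(x$sampling_times),
              max(x$sampling_times), x$lloq))
  invisible(x)
}

# Reference covariate summaries of the study population (n = 20): means and
# SDs of the continuous covariates, total kidney volume by sex, and the
# sex/race frequencies.  Continuous covariates are generated log-normally
# with moments matched to these values.
.covariate_reference <- list(
  AGE  = c(mean = 39,     sd = 11),
  WT   = c(mean = 66.98,  sd = 14.69),
  HT   = c(mean = 163.60, sd = 8.99),
  BSA  = c(mean = 1.72,   sd = 0.21),
  SCR  = c(mean = 0.77,   sd = 0.14),
  CRCL = c(mean = 103.43, sd = 22.63),
  TCV  = c(mean = 339.93, sd = 201.19),
  TKV_female = c(mean = 924.14, sd = 404.27),
  TKV_male   = c(mean = 822.18, sd = 486.22),
  p_female = 0.70,
  p_race = c(caucasian = 0.75, afro_american = 0.05, other = 0.20)
)

# Log-normal draws with arithmetic mean m and SD s (moment matching); s = 0
# degenerates to the constant m.
rlnorm_ms <- function(n, m, s) {
  if (s == 0) return(rep(m, n))
  sdlog2 <- log(1 + (s / m)^2)
  rlnorm(n, meanlog = log(m) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Sample subject covariates
#'
#' Draws demographic and clinical covariates reproducing the marginal
#' distributions of the study population: log-normal continuous covariates
#' matched to the reported mean/SD (total kidney volume sex-specifically),
#' 70% female, 75% Caucasian. Covariates have no effect on the model
#' parameters under the final model; they provide a true-negative test bed
#' for covariate screening (and optional effects can be injected via
#' [generate_trial()]).
#'
#' @param n number of subjects.
#' @param seed optional RNG seed (restores the RNG state on exit).
#' @param sd_scale multiplier on all continuous-covariate SDs; 0 gives every
#'   subject the reference mean values.
#' @return Data frame with columns AGE (y), WT (kg), HT (cm), BSA (m^2),
#'   SCR (mg/dL), CRCL (mL/min/1.73m^2), TKV (mL), TCV (mL), SEX (1 female,
#'   0 male), RACE (1 Caucasian, 2 Afro-American, 3 other).
#' @export
sample_covariates <- function(n, seed = NULL, sd_scale = 1) {
  local_seed(seed)
  ref <- .covariate_reference
  sex <- as.integer(runif(n) < ref$p_female)
  tkv <- numeric(n)
  nf <- sum(sex == 1L)
  tkv[sex == 1L] <- rlnorm_ms(nf, ref$TKV_female["mean"],
                              sd_scale * ref$TKV_female["sd"])
  tkv[sex == 0L] <- rlnorm_ms(n - nf, ref$TKV_male["mean"],
                              sd_scale * ref$TKV_male["sd"])
  race <- sample.int(3L, n, replace = TRUE, prob = ref$p_race)
  data.frame(
    AGE = rlnorm_ms(n, ref$AGE["mean"], sd_scale * ref$AGE["sd"]),
    WT = rlnorm_ms(n, ref$WT["mean"], sd_scale * ref$WT["sd"]),
    HT = rlnorm_ms(n, ref$HT["mean"], sd_scale * ref$HT["sd"]),
    BSA = rlnorm_ms(n, ref$BSA["mean"], sd_scale * ref$BSA["sd"]),
    SCR = rlnorm_ms(n, ref$SCR["mean"], sd_scale * ref$SCR["sd"]),
    CRCL = rlnorm_ms(n, ref$CRCL["mean"], sd_scale * ref$CRCL["sd"]),
    TKV = tkv, TCV = rlnorm_ms(n, ref$TCV["mean"], sd_scale * ref$TCV["sd"]),
    SEX = sex, RACE = race
  )
}

#' Sample individual parameters
#'
#' Realizes the exponential inter-individual variability model: `Rtotp` and
#' `kout` are multiplied by `exp(eta)` with independent zero-mean normal
#' `eta` of standard deviation `omega_Rtotp` / `omega_kout`; all other
#' parameters stay at their typical values.
#'
#' @param p a `nimo_params` object (typical values and omegas).
#' @param n number of individuals.
#' @param seed optional RNG seed.
#' @return A list of `n` `nimo_params` objects, each carrying its `eta`
#'   draws as an attribute.
#' @export
sample_individual <- function(p, n = 1, seed = NULL) {
  validate_params(p)
  local_seed(seed)
  eta1 <- rnorm(n, 0, p$omega_Rtotp)
  eta2 <- rnorm(n, 0, p$omega_kout)
  lapply(seq_len(n), function(i) {
    pi <- p
    pi$Rtotp <- p$Rtotp * exp(eta1[i])
    pi$kout <- p$kout * exp(eta2[i])
    attr(pi, "eta") <- c(eta_Rtotp = eta1[i], eta_kout = eta2[i])
    pi
  })
}

# Evaluate and restore the RNG state around seeded draws so that seeded
# generator calls do not perturb the caller's random stream.
local_seed <- function(seed) {
  if (is.null(seed)) return(invisible(NULL))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite number")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  restore <- if (is.null(old)) {
    quote(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  } else {
    bquote(assign(".Random.seed", .(old), envir = globalenv()))
  }
  do.call(on.exit, list(restore, add = TRUE), envir = parent.frame())
  set.seed(as.integer(seed %% .Machine$integer.max))
  invisible(NULL)
}
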