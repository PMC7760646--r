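test_that("a noise-free exact model collapses the VPC to a single curve", {
  p <- nimo_params(omega_Rtotp = 0, omega_kout = 0, sigma_log = 1e-9)
  trial <- generate_trial(p, small_design(), seed = 61)
  v <- pc_vpc(trial, p, n_sim = 60, seed = 1)
  # All percentiles coincide and the simulation bands have zero width.
  expect_equal(v$obs_p2.5, v$obs_p97.5, tolerance = 1e-6)
  expect_equal(v$sim_p50_lo, v$sim_p50_hi, tolerance = 1e-6)
  expect_equal(v$obs_p50, v$sim_p50_med, tolerance = 1e-6)
})

test_that("prediction correction aligns dose cohorts onto a common scale", {
  p <- nimo_params()
  trial <- generate_trial(p, trial_design(n_per_cohort = 4), seed = 62)
  v <- pc_vpc(trial, p, n_sim = 60, seed = 2)
  expect_equal(nrow(v), 23L)                 # one bin per sampling time
  expect_equal(sum(v$n), 4 * 4 * 23)
  # Percentiles are ordered within every bin and bands contain their median.
  expect_true(all(v$obs_p2.5 <= v$obs_p50 & v$obs_p50 <= v$obs_p97.5))
  expect_true(all(v$sim_p50_lo <= v$sim_p50_hi))
  expect_true(all(v$sim_p50_lo <= v$sim_p50_med &
                    v$sim_p50_med <= v$sim_p50_hi))
})

test_that("VPC inputs are validated and user bins are honoured", {
  p <- nimo_params()
  trial <- generate_trial(p, small_design(), seed = 63)
  expect_error(pc_vpc(trial, p, n_sim = 10), "at least 50")
  v <- pc_vpc(trial, p, n_sim = 50, seed = 3,
              bins = c(0, 12, 100, 700))
  expect_equal(nrow(v), 3L)
  # A break structure with an empty interval merges and warns.
  expect_warning(
    pc_vpc(trial, p, n_sim = 50, seed = 3,
           bins = c(0, 0.1, 0.2, 100, 700)),
    "merged")
})

test_that("replicate count controls the Monte-Carlo jitter of the bands", {
  p <- nimo_params()
  trial <- generate_trial(p, small_design(), seed = 64)
  edge <- function(n_sim, seed) {
    v <- pc_vpc(trial, p, n_sim = n_sim, seed = seed)
    v$sim_p50_lo
  }
  lo_small <- sapply(1:4, function(s) edge(50, s))
  lo_big <- sapply(1:4, function(s) edge(200, s + 10))
  jitter_small <- mean(apply(lo_small, 1, sd))
  jitter_big <- mean(apply(lo_big, 1, sd))
  expect_lt(jitter_big, jitter_small)
})

test_that("bootstrap with degenerate resampling reproduces the point fit", {
  p <- nimo_params()
  trial <- generate_trial(p, small_design(), seed = 65)
  fit <- nimo_fit(trial, init = p, fix = fix_small,
                  control = fast_ctl(bfgs_maxit = 30))
  n <- length(unique(trial$ID))
  rs <- matrix(rep(seq_len(n), each = 3), nrow = 3, byrow = FALSE)
  b <- nimo_bootstrap(trial, init = fit$estimates, n_resamples = 3,
                      fix = fix_small,
                      control = fast_ctl(bfgs_maxit = 4),
                      .resample_matrix = rs)
  expect_equal(b$n_failed, 0)
  for (nm in c("CL", "V1")) {
    # Identical resamples give bit-identical replicate fits.
    expect_identical(b$estimates[[nm]], rep(b$estimates[[nm]][1], 3))
    expect_equal(unname(b$estimates[[nm]]),
                 rep(coef(fit)[[nm]], 3), tolerance = 5e-2)
    expect_lte(b$summary[nm, "p2.5"], b$summary[nm, "median"])
    expect_lte(b$summary[nm, "median"], b$summary[nm, "p97.5"])
  }
  expect_error(nimo_bootstrap(trial, n_resamples = 1), "at least 2")
})

test_that("residual noise widens the bootstrap intervals", {
  width <- function(sig, seed) {
    p <- nimo_params(sigma_log = sig, omega_Rtotp = 0, omega_kout = 0)
    trial <- generate_trial(p, small_design(), seed = seed)
    fit <- nimo_fit(trial, init = p,
                    fix = setdiff(nimopk:::.all_par_names,
                                  c("CL", "V1", "sigma_log")),
                    control = fast_ctl(bfgs_maxit = 6))
    b <- nimo_bootstrap(trial, init = fit$estimates, n_resamples = 8,
                        seed = seed,
                        fix = setdiff(nimopk:::.all_par_names,
                                      c("CL", "V1", "sigma_log")),
                        control = fast_ctl(bfgs_maxit = 4))
    diff(b$summary["CL", c("p2.5", "p97.5")])
  }
  expect_lt(width(0.1, 66), width(0.4, 66))
})

test_that("weighted residuals are calibrated under the true model", {
  p <- nimo_params()
  trial <- generate_trial(p, trial_design(), seed = 67)
  fit <- nimo_fit(trial, init = p, fix = fix_small,
                  control = fast_ctl(bfgs_maxit = 12))
  res <- gof_residuals(trial, fit)
  expect_equal(nrow(res), 460L)
  expect_true(all(c("PRED", "IPRED", "IWRES", "CWRES") %in% names(res)))
  # IWRES approximately standard normal for a well-specified model.
  expect_equal(mean(res$IWRES), 0, tolerance = 0.1)
  expect_equal(sd(res$IWRES), 1, tolerance = 0.1)
  expect_equal(mean(res$CWRES), 0, tolerance = 0.25)

  # Noise-free data with an exact model: IWRES is identically zero.
  p0 <- nimo_params(omega_Rtotp = 0, omega_kout = 0, sigma_log = 0)
  tr0 <- generate_trial(p0, small_design(), seed = 68)
  p0f <- p0
  p0f$sigma_log <- 1e-6
  fit0 <- structure(list(
    estimates = p0f, covariate_model = list(),
    ebe = matrix(0, 8, 2), data_hash = nimopk:::data_hash(tr0)
  ), class = "nimo_fit")
  res0 <- gof_residuals(tr0, fit0)
  expect_lt(max(abs(res0$IWRES)), 1e-3)

  # Misspecification (mediator forced off) inflates the residuals.
  pmis <- fit$estimates
  pmis$Smax <- 0
  fit_mis <- structure(list(
    estimates = pmis, covariate_model = list(),
    ebe = fit$ebe, data_hash = fit$data_hash
  ), class = "nimo_fit")
  res_mis <- gof_residuals(trial, fit_mis)
  expect_gt(abs(mean(res_mis$IWRES)), abs(mean(res$IWRES)))
  expect_gt(sd(res_mis$IWRES), sd(res$IWRES))
})
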