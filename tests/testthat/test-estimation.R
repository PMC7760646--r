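make_subject <- function(p, dose = 100, times = c(1, 24, 168, 672),
                         conc = NULL) {
  pd <- params_for_dose(p, dose)
  sim <- nimo_simulate(pd, dose_event(dose), times)
  if (is.null(conc)) conc <- sim$total_central_conc
  list(id = 1, dose = dose,
       doses = data.frame(amount = dose, start = 0, duration = 0.5),
       obs = data.frame(time = times, conc = conc),
       pred = sim$total_central_conc)
}

test_that("the individual likelihood is the Gaussian density on log scale", {
  p <- nimo_params()
  # A single observation equal to its prediction contributes log(2 pi s^2).
  s1 <- make_subject(p, times = 24)
  expect_equal(individual_neg2ll(s1, p), log(2 * pi * p$sigma_log^2),
               tolerance = 1e-8)
  # Doubling sigma at fixed residuals scales the quadratic term by 1/4.
  s2 <- make_subject(p)
  s2$obs$conc <- s2$pred * exp(0.3)          # constant log-residual 0.3
  m <- nrow(s2$obs)
  quad1 <- individual_neg2ll(s2, p) - m * log(2 * pi * p$sigma_log^2)
  p2 <- p; p2$sigma_log <- 2 * p$sigma_log
  quad2 <- individual_neg2ll(s2, p2) - m * log(2 * pi * p2$sigma_log^2)
  expect_equal(quad2 / quad1, 1 / 4, tolerance = 1e-8)
  # Literal transcription of the summed Gaussian log-density.
  set.seed(31)
  s3 <- make_subject(p)
  s3$obs$conc <- s3$pred * exp(rnorm(4, 0, 0.4))
  hand <- -2 * sum(dnorm(log(s3$obs$conc), mean = log(s3$pred),
                         sd = p$sigma_log, log = TRUE))
  expect_equal(individual_neg2ll(s3, p), hand, tolerance = 1e-6)
  # Non-positive observations are a data error.
  s4 <- make_subject(p)
  s4$obs$conc[2] <- 0
  expect_error(individual_neg2ll(s4, p), "positive")
})

test_that("the marginal likelihood degenerates correctly without IIV", {
  p <- nimo_params(omega_Rtotp = 0, omega_kout = 0)
  trial <- generate_trial(p, small_design(), seed = 41)
  subs <- nimopk:::subject_records(trial)
  by_hand <- sum(vapply(subs, function(s) {
    individual_neg2ll(s, params_for_dose(p, s$dose))
  }, numeric(1)))
  expect_equal(marginal_neg2ll(trial, p), by_hand, tolerance = 1e-6)
})

test_that("an uninformative subject does not change the objective", {
  p <- nimo_params()
  trial <- generate_trial(p, small_design(), seed = 43)
  base <- marginal_neg2ll(trial, p)
  extra <- trial[trial$ID == 1, ]
  extra$ID <- 99
  extra$MDV <- 1L                           # all observations missing
  both <- rbind(as.data.frame(trial), as.data.frame(extra))
  class(both) <- c("nimo_trial", "data.frame")
  expect_equal(marginal_neg2ll(both, p), base, tolerance = 1e-8)
})

test_that("Laplace agrees with adaptive quadrature on a one-eta problem", {
  # One subject, one random effect (on kout).  In the linear limit the
  # random effect is inert, so Laplace and quadrature coincide exactly;
  # with the mediator active the exact-Hessian Laplace tracks quadrature
  # closely and the Gauss-Newton variant somewhat more loosely.
  design <- trial_design(n_per_cohort = 1, dose_levels = 100)

  plin <- nimo_params(Rtot = 0, Rtotp = 0, Smax = 0, omega_Rtotp = 0,
                      omega_kout = 0.5, sigma_log = 0.3)
  tr_lin <- generate_trial(plin, design, seed = 22)
  subs <- nimopk:::subject_records(tr_lin)
  expect_equal(marginal_neg2ll(tr_lin, plin, hessian = "exact"),
               individual_neg2ll(subs[[1]], plin), tolerance = 1e-6)

  p <- nimo_params(omega_Rtotp = 0, omega_kout = 0.5, sigma_log = 0.3)
  tr <- generate_trial(p, design, seed = 21)
  ld <- nimopk:::build_likelihood_data(tr)
  pm <- nimopk:::build_pmat(ld, p, list())
  io <- 1:ld$obs_ptr[2]
  ind <- function(eta) {
    pv <- pm[1, ]
    pv["kout"] <- pv["kout"] * exp(eta)
    .tmdd_subject_m2ll_cpp(pv, p$sigma_log, ld$obs_t[io], ld$obs_logdv[io],
                           ld$dose_amt, ld$dose_start, ld$dose_dur,
                           1e-10, 1e-12, 1e-12)
  }
  lik <- Vectorize(function(eta) exp(-0.5 * ind(eta)) *
                     dnorm(eta, 0, p$omega_kout))
  quad <- -2 * log(integrate(lik, -8, 8, rel.tol = 1e-10)$value)
  expect_equal(marginal_neg2ll(tr, p, hessian = "exact",
                               rtol = 1e-10, atol = 1e-12),
               quad, tolerance = 0.05 / abs(quad))
  expect_equal(marginal_neg2ll(tr, p, hessian = "gn",
                               rtol = 1e-10, atol = 1e-12),
               quad, tolerance = 0.3 / abs(quad))
})

test_that("noise-free data are recovered to well under 1%", {
  p <- nimo_params(omega_Rtotp = 0, omega_kout = 0, sigma_log = 0)
  trial <- generate_trial(p, small_design(), seed = 17)
  init <- nimo_params(CL = p$CL * 1.4, V1 = p$V1 * 0.8,
                      omega_Rtotp = 0, omega_kout = 0, sigma_log = 0.01)
  fit <- nimo_fit(trial, init = init,
                  fix = setdiff(nimopk:::.all_par_names, c("CL", "V1")))
  expect_equal(coef(fit)[["CL"]], p$CL, tolerance = 0.01)
  expect_equal(coef(fit)[["V1"]], p$V1, tolerance = 0.01)
  expect_equal(fit$convergence$status, 0)
})

fake_fit <- function(ofv, n_params, hash = "h") {
  structure(list(ofv = ofv, n_params = n_params, data_hash = hash),
            class = "nimo_fit")
}

test_that("model comparison applies the chi-square and AIC rules", {
  # Nested: a drop of 7.9 > 7.879 for 1 df accepts the larger model.
  small <- fake_fit(1000, 5)
  large <- fake_fit(1000 - 7.9, 6)
  cmp <- compare_models(small, large, nested = TRUE)
  expect_true(cmp$accept_larger)
  expect_equal(cmp$preferred, "B")
  expect_equal(cmp$threshold, qchisq(0.995, 1), tolerance = 1e-6)
  # No improvement: reject the larger model.
  cmp0 <- compare_models(small, fake_fit(1000, 6), nested = TRUE)
  expect_false(cmp0$accept_larger)
  expect_equal(cmp0$preferred, "A")
  # Antisymmetry and reflexive tie.
  swap <- compare_models(large, small, nested = TRUE)
  expect_equal(swap$preferred, "A")  # the larger model is now argument A
  expect_equal(swap$delta_ofv, cmp$delta_ofv)
  self <- compare_models(small, small, nested = TRUE)
  expect_equal(self$preferred, "tie")
  # Non-nested: lower AIC wins; equal OFV prefers fewer parameters.
  a <- fake_fit(1000, 5)
  b <- fake_fit(1000, 7)
  expect_equal(compare_models(a, b, nested = FALSE)$preferred, "A")
  expect_equal(compare_models(b, a, nested = FALSE)$preferred, "B")
  # Different data: invalid comparison.
  expect_error(compare_models(a, fake_fit(1, 1, hash = "other"),
                              nested = FALSE), "different datasets")
})

test_that("the shrinkage gate excludes unsuitable parameters from screening", {
  p <- nimo_params()
  trial <- generate_trial(p, small_design(), seed = 47)
  base <- structure(list(
    ofv = 100, n_params = 3, data_hash = nimopk:::data_hash(trial),
    estimates = p, fixed_mask = character(0),
    eta_shrinkage = c(eta_Rtotp = 60, eta_kout = 45)
  ), class = "nimo_fit")
  res <- scm(trial, base, covariates = c("WT", "AGE"),
             parameters = c("Rtotp", "kout"))
  expect_length(res$selected, 0)
  expect_match(res$reason, "shrinkage gate")
  expect_setequal(res$skipped, c("Rtotp", "kout"))
})

test_that("fitted models expose coherent summaries and predictions", {
  p <- nimo_params()
  trial <- generate_trial(p, small_design(), seed = 53)
  fit <- nimo_fit(trial, init = p, fix = fix_small,
                  control = fast_ctl(bfgs_maxit = 8))
  expect_s3_class(fit, "nimo_fit")
  expect_true(is.finite(fit$ofv))
  expect_equal(fit$n_subjects, 8)
  expect_equal(dim(fit$ebe), c(8L, 2L))
  expect_equal(fit$aic, fit$ofv + 2 * fit$n_params)
  expect_lt(fit$eta_shrinkage[["eta_Rtotp"]], 100)
  expect_output(print(fit), "OFV")
  expect_output(print(summary(fit)), "shrinkage")
  expect_equal(as.numeric(logLik(fit)), -fit$ofv / 2)

  pr <- predict(fit, trial, type = "pred")
  ipr <- predict(fit, trial, type = "ipred")
  expect_equal(nrow(pr), fit$n_obs)
  expect_true(all(pr$pred > 0))
  # Individual predictions fit the data at least as well as population ones.
  expect_lte(mean((log(ipr$DV) - log(ipr$ipred))^2),
             mean((log(pr$DV) - log(pr$pred))^2))
  sims <- simulate(fit, nsim = 2, seed = 5, data = trial)
  expect_length(sims, 2)
  expect_false(identical(sims[[1]]$DV, sims[[2]]$DV))
  expect_identical(sims[[1]]$TIME, trial$TIME)
})
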