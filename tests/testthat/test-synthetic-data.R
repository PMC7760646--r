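test_that("individual parameters follow the exponential IIV model", {
  p <- nimo_params()
  # Zero variability: individuals coincide with the typical subject.
  p0 <- nimo_params(omega_Rtotp = 0, omega_kout = 0)
  ind <- sample_individual(p0, n = 3, seed = 1)
  for (x in ind) expect_equal(unclass(x)[.e <- names(unclass(p0))],
                              unclass(p0)[.e])
  # Fixed seed: bit-identical repeats.
  a <- sample_individual(p, n = 5, seed = 99)
  b <- sample_individual(p, n = 5, seed = 99)
  expect_identical(a, b)
  # Realized log-scale SD matches omega at Monte-Carlo scale.
  big <- sample_individual(p, n = 10000, seed = 7)
  lr <- log(vapply(big, `[[`, numeric(1), "Rtotp") / p$Rtotp)
  lk <- log(vapply(big, `[[`, numeric(1), "kout") / p$kout)
  expect_equal(sd(lr), 1.35, tolerance = 0.03 / 1.35)
  expect_equal(sd(lk), 1.97, tolerance = 0.04 / 1.97)
  expect_equal(mean(lr), 0, tolerance = 0.05)
})

test_that("covariates reproduce the study population distributions", {
  cv <- sample_covariates(10000, seed = 11)
  expect_equal(mean(cv$WT), 66.98, tolerance = 1 / 66.98)
  expect_equal(sd(cv$WT), 14.69, tolerance = 0.05)
  expect_equal(mean(cv$SEX), 0.70, tolerance = 0.02 / 0.70)
  expect_equal(mean(cv$RACE == 1), 0.75, tolerance = 0.03)
  expect_equal(mean(cv$AGE), 39, tolerance = 0.02)
  # Sex-specific kidney volumes.
  expect_equal(mean(cv$TKV[cv$SEX == 1]), 924.14, tolerance = 0.03)
  expect_equal(mean(cv$TKV[cv$SEX == 0]), 822.18, tolerance = 0.05)
  expect_true(all(cv$WT > 0 & cv$SCR > 0 & cv$TKV > 0))
  # Degenerate draw: all subjects at the reference means.
  cv0 <- sample_covariates(5, seed = 2, sd_scale = 0)
  expect_equal(var(cv0$WT), 0)
  expect_equal(cv0$WT[1], 66.98)
})

test_that("the default virtual trial matches the study design", {
  trial <- generate_trial(nimo_params(), trial_design(), seed = 3)
  expect_s3_class(trial, "nimo_trial")
  ids <- unique(trial$ID)
  expect_length(ids, 20L)
  expect_equal(sort(unique(trial$DOSE)), c(50, 100, 200, 400))
  obs <- trial[trial$EVID == 0 & trial$MDV == 0, ]
  expect_equal(nrow(obs), 460L)           # 20 subjects x 23 samples
  expect_equal(as.integer(table(obs$ID)), rep(23L, 20L))
  # One dosing row and one flagged pre-dose record per subject.
  expect_equal(sum(trial$EVID == 1), 20L)
  expect_equal(sum(trial$EVID == 0 & trial$MDV == 1), 20L)
  expect_true(all(obs$DV > 0))
  expect_true(all(trial$RATE[trial$EVID == 1] ==
                    trial$AMT[trial$EVID == 1] / 0.5))
  # Determinism under a fixed seed.
  trial2 <- generate_trial(nimo_params(), trial_design(), seed = 3)
  expect_identical(as.data.frame(trial), as.data.frame(trial2))
})

test_that("noise-free trials reproduce the typical-model predictions", {
  p <- nimo_params(omega_Rtotp = 0, omega_kout = 0, sigma_log = 0)
  design <- small_design()
  trial <- generate_trial(p, design, seed = 5)
  obs <- trial[trial$EVID == 0 & trial$MDV == 0, ]
  for (id in unique(obs$ID)) {
    d <- obs[obs$ID == id, ]
    pd <- params_for_dose(p, d$DOSE[1])
    sim <- nimo_simulate(pd, dose_event(d$DOSE[1]), d$TIME)
    expect_equal(d$DV, sim$total_central_conc, tolerance = 1e-8)
  }
  # Dose-monotone Cmax across the cohorts that share the typical V1
  # (the 50 mg arm has its own cohort volume and peaks higher than
  # dose-proportionality would suggest).
  cmax <- tapply(obs$DV, obs$DOSE, max)
  cmax <- cmax[order(as.numeric(names(cmax)))]
  expect_true(all(diff(cmax[c("100", "200", "400")]) > 0))
  expect_gt(cmax[["50"]], cmax[["100"]] / 2)
})

test_that("the realized residual error matches its generating value", {
  p <- nimo_params(omega_Rtotp = 0, omega_kout = 0)
  design <- trial_design(n_per_cohort = 250)   # 1000 subjects
  trial <- generate_trial(p, design, seed = 8)
  obs <- trial[trial$EVID == 0 & trial$MDV == 0, ]
  # With IIV off, log(obs/pred) is exactly the residual draw.
  pred <- numeric(nrow(obs))
  for (dose in unique(obs$DOSE)) {
    pd <- params_for_dose(p, dose)
    tt <- sort(unique(obs$TIME[obs$DOSE == dose]))
    sim <- nimo_simulate(pd, dose_event(dose), tt)
    pred[obs$DOSE == dose] <- sim$total_central_conc[
      match(obs$TIME[obs$DOSE == dose], tt)]
  }
  expect_equal(sd(log(obs$DV / pred)), 0.48, tolerance = 0.02 / 0.48)
})

test_that("injected covariate effects act on the individual parameters", {
  p <- nimo_params(omega_Rtotp = 0, omega_kout = 0, sigma_log = 0)
  eff <- list(covariate_term("CL", "WT", "power", theta = 0.75,
                             center = 65.7))
  trial <- generate_trial(p, small_design(), seed = 13,
                          covariate_effects = eff)
  obs <- trial[trial$EVID == 0 & trial$MDV == 0, ]
  # Heavier subjects clear faster: late concentrations decrease with weight
  # within a dose cohort.
  late <- obs[obs$TIME == 672, ]
  for (dose in unique(late$DOSE)) {
    d <- late[late$DOSE == dose, ]
    if (nrow(d) > 1) {
      expect_true(all(diff(d$DV[order(d$WT)]) < 0))
    }
  }
})
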