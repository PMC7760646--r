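test_that("the solver reproduces the closed-form linear infusion solution", {
  p <- nimo_params(Rtot = 0, Rtotp = 0, Smax = 0)
  times <- c(0.25, 0.5, 1, 2, 6, 12, 24, 96, 240, 672, 1000)
  sim <- nimo_simulate(p, dose_event(100), times, rtol = 1e-10, atol = 1e-12)
  ref <- linear2cpt_amounts(p$CL, p$V1, p$V2, p$Q, 100, 0.5, times)
  expect_equal(sim$free_central_conc, ref[, 1L] / p$V1, tolerance = 1e-6)
  expect_equal(sim$peripheral_conc, ref[, 2L] / p$V2, tolerance = 1e-6)
})

test_that("superposition holds in the linear limit", {
  p <- nimo_params(Rtot = 0, Rtotp = 0, Smax = 0)
  times <- seq(0, 500, by = 2.5)
  s50 <- nimo_simulate(p, dose_event(50), times)
  s100 <- nimo_simulate(p, dose_event(100), times)
  expect_equal(2 * s50$free_central_conc, s100$free_central_conc,
               tolerance = 1e-8)
})

test_that("mass balance holds in the linear limit", {
  p <- nimo_params(Rtot = 0, Rtotp = 0, Smax = 0)
  # Extend the horizon until the residual amount is negligible relative to
  # the dose, then CL * AUC must equal the dose.
  horizon <- 10000
  times <- seq(0, horizon, by = 1)
  sim <- nimo_simulate(p, dose_event(100), times)
  residual <- sim$free_central_conc[length(times)] * p$V1 +
    sim$peripheral_conc[length(times)] * p$V2
  expect_lt(residual, 1e-4 * 100)
  auc <- sum(diff(times) * (head(sim$free_central_conc, -1) +
                              sim$free_central_conc[-1]) / 2)
  expect_equal(p$CL * auc, 100, tolerance = 5e-3)
})

test_that("the one-compartment bolus limit decays mono-exponentially", {
  p <- nimo_params(Q = 1e-9, Rtot = 0, Rtotp = 0, Smax = 0)
  times <- seq(1, 300, by = 1)
  sim <- nimo_simulate(p, dose_event(100, duration = 0.01), times)
  expect_equal(sim$free_central_conc,
               100 / p$V1 * exp(-p$CL / p$V1 * times), tolerance = 1e-3)
})

test_that("time above a threshold interpolates crossings linearly", {
  # Piecewise-linear series rising above the threshold at t = 1 and falling
  # below at t = 3.
  sim <- data.frame(time = 0:4,
                    free_central_conc = c(0, 10, 20, 10, 0),
                    total_central_conc = c(0, 10, 20, 10, 0))
  expect_equal(time_above_threshold(sim, 10), 2)
  expect_equal(time_above_threshold(sim, 5), 3)
  below <- data.frame(time = 0:4, free_central_conc = rep(1, 5),
                      total_central_conc = rep(1, 5))
  expect_equal(time_above_threshold(below, 10), 0)
  expect_error(time_above_threshold(below, -1), "positive")
  expect_error(time_above_threshold(below[0, ], 1), "non-empty")
})

test_that("typical-value profiles are finite, unimodal and decaying", {
  p <- nimo_params()
  sim <- nimo_simulate(p, dose_event(100), seq(0, 1000, by = 0.5))
  y <- sim$total_central_conc
  expect_true(all(is.finite(y)))
  post <- y[sim$time >= 0.5]
  expect_equal(which.max(post), 1L)          # peak at end of infusion
  expect_true(all(diff(post) <= 1e-9))       # monotone decline afterwards
  expect_lt(y[length(y)], 0.05 * max(y))     # approaches zero by 1000 h
})

test_that("dose sweep metrics behave as the model dictates", {
  # Linear limit: AUC strictly proportional to dose.
  plin <- nimo_params(Rtot = 0, Rtotp = 0, Smax = 0, v1_dose50_change = 0)
  swl <- dose_sweep(plin, doses = c(50, 100, 200, 400), horizon = 500,
                    dt = 1)
  ratio <- swl$metrics$auc_total / swl$metrics$dose
  expect_equal(max(ratio) / min(ratio), 1, tolerance = 1e-6)

  # Full model: mediator peak is non-decreasing in dose and approaches the
  # stimulation ceiling 1 + Smax.
  p <- nimo_params()
  sw <- dose_sweep(p, horizon = 1000, dt = 0.5)
  peaks <- vapply(sw$profiles, function(s) max(s$mediator), numeric(1))
  expect_true(all(diff(peaks) >= -1e-9))
  expect_lt(max(peaks), 1 + p$Smax)
  # Saturation: the 1200 mg peak reaches ~89% of the stimulation ceiling
  # (3.7186, cross-checked against an independent lsoda solution).
  expect_gt(peaks[["1200"]], 0.85 * (1 + p$Smax))
  # The 50 mg V1 adjustment applies only to the 50 mg arm.
  expect_equal(attr(sw$profiles[["50"]], "params")$V1,
               p$V1 * (1 - p$v1_dose50_change))
  expect_equal(attr(sw$profiles[["100"]], "params")$V1, p$V1)
})

test_that("reported metrics are stable under tolerance refinement", {
  p <- nimo_params()
  m1 <- dose_sweep(p, doses = c(100, 400), horizon = 1000, dt = 0.5,
                   rtol = 1e-8, atol = 1e-10)$metrics
  m2 <- dose_sweep(p, doses = c(100, 400), horizon = 1000, dt = 0.5,
                   rtol = 5e-9, atol = 5e-11)$metrics
  for (col in c("cmax_total", "auc_total", "time_above")) {
    expect_equal(m1[[col]], m2[[col]], tolerance = 1e-3 * 0.1)
  }
})

test_that("simulation inputs are validated", {
  p <- nimo_params()
  expect_error(nimo_simulate(p, dose_event(100), c(3, 2, 1)), "sorted")
  expect_error(nimo_simulate(p, data.frame(x = 1), 0:10), "amount")
  expect_error(dose_event(-5), "positive")
  expect_error(dose_event(100, duration = 0), "positive")
  expect_error(nimo_simulate(p, dose_event(100), 0:10, rtol = 0), "positive")
})

test_that("the compiled solver agrees with an independent stiff integrator", {
  p <- nimo_params()
  rhs_ref <- function(t, A, pp, rate) {
    list(hand_rhs(A, pp, rate(t)))
  }
  times <- c(0.5, 2, 24, 168, 672)
  for (dose in c(50, 400)) {
    ref <- deSolve::ode(c(0, 0, 1), c(0, times), rhs_ref, p,
                        rate = function(t) ifelse(t < 0.5, dose / 0.5, 0),
                        method = "lsoda", rtol = 1e-10, atol = 1e-12)
    sim <- nimo_simulate(p, dose_event(dose), times, rtol = 1e-10,
                         atol = 1e-12)
    expect_equal(sim$free_central_conc, ref[-1, 2] / p$V1, tolerance = 1e-6)
    expect_equal(sim$mediator, ref[-1, 4], tolerance = 1e-6)
  }
})
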