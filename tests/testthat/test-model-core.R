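test_that("the system is at rest before dosing", {
  p <- nimo_params()
  d <- tmdd_rhs(c(0, 0, 1), p, infusion_rate = 0)
  expect_equal(unname(d), c(0, 0, 0))
})

test_that("rhs matches a literal transcription of the model equations", {
  p <- nimo_params()
  # Typical values, 100 mg in the central compartment, mediator at baseline.
  expect_equal(unname(tmdd_rhs(c(100, 0, 1), p, 0)),
               hand_rhs(c(100, 0, 1), p, 0), tolerance = 1e-12)
  # Random states, parameters and infusion rates.
  set.seed(71)
  for (i in 1:25) {
    pr <- nimo_params(CL = runif(1, 1e-3, 0.1), V1 = runif(1, 0.5, 5),
                      V2 = runif(1, 5e-3, 2), Q = runif(1, 1e-3, 0.2),
                      Kss = runif(1, 1, 40), kint = runif(1, 1e-4, 0.1),
                      Rtot = runif(1, 0, 10), Rtotp = runif(1, 0, 2000),
                      kout = runif(1, 1e-3, 0.5), Smax = runif(1, 0, 5),
                      S50 = runif(1, 1, 20), gamma = sample(1:3, 1))
    st <- c(runif(1, 0, 500), runif(1, 0, 5), runif(1, 1, 1 + pr$Smax))
    rate <- sample(c(0, 200), 1)
    expect_equal(unname(tmdd_rhs(st, pr, rate)), hand_rhs(st, pr, rate),
                 tolerance = 1e-10)
    # QSS correction denominators are always >= 1.
    C1 <- st[1] / pr$V1
    C2 <- st[2] / pr$V2
    expect_gte(1 + pr$Rtot * pr$Kss / (pr$Kss + C1)^2, 1)
    expect_gte(1 + pr$Rtotp * pr$Kss / (pr$Kss + C2)^2, 1)
  }
})

test_that("rhs reduces to the linear two-compartment model without targets", {
  p <- nimo_params(Rtot = 0, Rtotp = 0, Smax = 0)
  set.seed(5)
  for (i in 1:10) {
    st <- c(runif(1, 0, 200), runif(1, 0, 3), 1)
    rate <- runif(1, 0, 400)
    d <- tmdd_rhs(st, p, rate)
    expect_equal(d[["A1"]],
                 rate - (p$CL + p$Q) / p$V1 * st[1] + p$Q / p$V2 * st[2],
                 tolerance = 1e-12)
    expect_equal(d[["A2"]], p$Q / p$V1 * st[1] - p$Q / p$V2 * st[2],
                 tolerance = 1e-12)
    expect_equal(d[["A3"]], 0)
  }
})

test_that("rhs rejects invalid inputs", {
  p <- nimo_params()
  expect_error(tmdd_rhs(c(NA, 0, 1), p, 0), "finite")
  expect_error(tmdd_rhs(c(0, 0, 1), p, -1), "non-negative")
  bad <- nimo_params()
  bad$V1 <- -1
  expect_error(tmdd_rhs(c(0, 0, 1), bad, 0), "positive")
})

test_that("total concentration obeys the binding identities", {
  p <- nimo_params()
  expect_equal(total_concentration(0, p), 0)
  # Half-saturation: at C = Kss the bound part is exactly Rtot / 2.
  A_half <- p$Kss * p$V1
  expect_equal(total_concentration(A_half, p), p$Kss + p$Rtot / 2)
  # Saturation asymptote: total - free -> Rtot from below.
  A <- seq(0, 1e4, length.out = 200)
  tot <- total_concentration(A, p)
  free <- A / p$V1
  expect_true(all(diff(tot) > 0))
  expect_true(all(tot - free < p$Rtot))
  expect_equal(tot[200] - free[200], p$Rtot, tolerance = 1e-2)
  expect_error(total_concentration(-1, p), "non-negative")
})

test_that("derived distribution and binding quantities are exact", {
  # Steady-state volume from the published central and peripheral volumes.
  expect_equal(signif(steady_state_volume(nimo_params()), 3), 2.64)
  expect_equal(steady_state_volume(nimo_params(V1 = 1, V2 = 1e-12)), 1,
               tolerance = 1e-9)
  # Bootstrap-median volumes sum to 2.66 L.
  expect_equal(signif(steady_state_volume(nimo_params(V1 = 2.65,
                                                      V2 = 9.52e-3)), 3),
               2.66)
  # In-vitro dissociation constant of nimotuzumab.
  b <- binding_kinetics(kon = 5.2e4, koff = 1.1e-3)
  expect_equal(signif(dissociation_constant(b), 2), 2.1e-8)
  expect_equal(dissociation_constant(binding_kinetics(kon = 1, koff = 1)), 1)
  expect_equal(dissociation_constant(binding_kinetics(kon = 5.2e4,
                                                      koff = 2.2e-3)),
               2.2e-3 / 5.2e4)
  expect_error(binding_kinetics(kon = 0), "positive")
  # Molar/mass interconversion at the 150 kDa antibody weight.
  expect_equal(molar_to_mass(100e-9, 150e3), 15)
  expect_equal(molar_to_mass(1e-9, 150e3), 0.15)
  expect_equal(molar_to_mass(0, 150e3), 0)
  expect_error(molar_to_mass(-1, 150e3), "non-negative")
})

test_that("parameter validation catches invariant violations", {
  expect_error(nimo_params(CL = 0), "positive")
  expect_error(nimo_params(Smax = -0.1), "non-negative")
  expect_error(nimo_params(omega_kout = -1), "non-negative")
  expect_error(nimo_params(gamma = 0), "positive")
  expect_error(nimo_params(CL = NaN), "non-finite")
  expect_silent(validate_params(nimo_params(Smax = 0)))
})

test_that("parameters survive a YAML and JSON round trip", {
  p <- nimo_params(CL = 0.0123, Smax = 2.5, v1_dose50_mode = "increase")
  for (ext in c("yaml", "json")) {
    path <- file.path(tempdir(), paste0("pars.", ext))
    write_params(p, path)
    q <- read_params(path)
    expect_equal(unclass(q), unclass(p), tolerance = 1e-12)
  }
  bad <- file.path(tempdir(), "bad.yaml")
  yaml::write_yaml(list(CL = 1, nonsense = 2), bad)
  expect_error(read_params(bad), "unknown parameter")
})

test_that("the mediator is inert without stimulation and bounded with it", {
  times <- seq(0, 800, by = 1)
  p0 <- nimo_params(Smax = 0)
  sim0 <- nimo_simulate(p0, dose_event(400), times)
  expect_equal(sim0$mediator, rep(1, length(times)), tolerance = 1e-9)
  for (dose in c(50, 400, 1200)) {
    p <- nimo_params()
    sim <- nimo_simulate(p, dose_event(dose), times)
    expect_true(all(sim$mediator >= 1 - 1e-9))
    expect_true(all(sim$mediator <= 1 + p$Smax + 1e-9))
  }
})
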