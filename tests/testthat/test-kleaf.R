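test_that("extract_E averages the steady window and refuses non-steady", {
  # noiseless plateau at 5.0: E is exactly 5.0
  sim0 <- simulate_flow(trace_spec(E_plateau = 5, rise_tau_s = 30,
                                   noise_sd = 0, seed = 1))
  st0 <- classify_trace(sim0$trace)
  expect_identical(st0$curve_class, "D")
  expect_equal(extract_E(sim0$trace, st0), 5, tolerance = 1e-6)

  # noisy plateau at the rice magnitude: recovery within 3 sd / sqrt(n)
  sim <- simulate_flow(trace_spec(E_plateau = 8.75, noise_sd = 0.1, seed = 2))
  st <- classify_trace(sim$trace)
  E <- extract_E(sim$trace, st)
  expect_lt(abs(E - 8.75), 3 * 0.1 / sqrt(300))

  simC <- simulate_flow(trace_spec(duration_s = 840, rise_tau_s = 90,
                                   seed = 3))
  stC <- classify_trace(simC$trace)
  expect_error(extract_E(simC$trace, stC), "non-steady")
})

test_that("K_leaf follows E / (0 - psi_final) with its scale laws", {
  k <- compute_kleaf(8.7, -0.31, T_leaf_C = 25)
  expect_equal(k$K_raw, 8.7 / 0.31)
  expect_equal(round(k$K_raw, 2), 28.06)
  expect_equal(k$K_25, k$K_raw)           # 25 C: viscosity factor is 1
  expect_equal(k$viscosity_factor, 1)

  expect_equal(compute_kleaf(0, -0.3)$K_raw, 0)
  expect_error(compute_kleaf(8.7, 0.1), "domain error")
  expect_error(compute_kleaf(-1, -0.3), "domain error")

  # linear in E, hyperbolic in psi
  for (c_ in c(0.5, 2, 7)) {
    expect_equal(compute_kleaf(c_ * 8.7, -0.31)$K_raw,
                 c_ * compute_kleaf(8.7, -0.31)$K_raw)
  }
  psis <- c(-0.17, -0.31, -0.45)
  Ks <- sapply(psis, function(p) compute_kleaf(8.7, p)$K_raw)
  expect_true(all(diff(Ks) < 0))          # more negative psi -> smaller K
  Es <- c(2, 5, 9)
  expect_true(all(diff(sapply(Es, function(e)
    compute_kleaf(e, -0.31)$K_raw)) > 0))
})

test_that("viscosity normalization uses a sound pure-water correlation", {
  expect_equal(viscosity_factor_25C(25), 1)
  expect_lt(viscosity_factor_25C(35), 1)  # warmer water is less viscous
  expect_gt(viscosity_factor_25C(15), 1)
  # value near the handbook viscosity of water at 25 C (0.890 mPa s)
  expect_lt(abs(water_viscosity(25) - 0.890), 0.01)
  # correlation evaluated independently of the function under test
  eta <- function(TC) exp(-3.7188 + 578.919 / (TC + 273.15 - 137.546))
  expect_equal(water_viscosity(20) / water_viscosity(25),
               eta(20) / eta(25), tolerance = 1e-12)
  expect_equal(signif(water_viscosity(20) / water_viscosity(25), 4), 1.123)

  # normalize then un-normalize is the identity
  K <- 28.06
  for (TC in c(15, 22, 27, 33, 40))
    expect_equal(normalize_to_25C(K, TC) / viscosity_factor_25C(TC), K,
                 tolerance = 1e-12)
  expect_error(water_viscosity(-5), "parameter error")
  expect_error(water_viscosity(120), "parameter error")
})

test_that("hydrostatic pressure of small height offsets is rho g h", {
  expect_equal(hydrostatic_pressure_kPa(0.02), 0.196, tolerance = 1e-12)
  expect_equal(hydrostatic_pressure_kPa(0), 0)
  expect_equal(hydrostatic_pressure_kPa(-0.02), -0.196, tolerance = 1e-12)
})

test_that("sensitivity grid is linear in E and hyperbolic in psi", {
  g <- sensitivity_grid(8.7, -0.31)
  ge <- g[g$parameter == "E", ]
  fit <- lm(K_leaf ~ value, data = ge)
  expect_lt(sum(resid(fit)^2), 1e-20)              # exactly linear
  expect_equal(unname(coef(fit)[1]), 0, tolerance = 1e-10)  # through origin
  # grid anchor reproduces the reference K
  expect_equal(g$K_leaf[g$parameter == "E" & g$rel_offset == 0],
               compute_kleaf(8.7, -0.31)$K_raw)
  gp <- g[g$parameter == "psi_final", ]
  expect_equal(gp$K_leaf, 8.7 / abs(gp$value), tolerance = 1e-12)
  expect_error(sensitivity_grid(8.7, -0.31, rel_range = c(-1.1, 0, 1)),
               "domain error")
})

test_that("percent change reproduces the environment-effect arithmetic", {
  expect_equal(round(percent_change(26.8, 16.0)), 40)
  expect_equal(round(percent_change(27.1, 23.0), 1), 15.1)
  expect_equal(percent_change(5, 5), 0)
  expect_error(percent_change(0, 1), "domain error")
})
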