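test_that("ATP accounting reproduces the hand-computed arithmetic chain exactly", {
  p <- membrane_params()
  # pure arithmetic: no integration involved, so the chain must be exact
  for (Q in c(1.429e-6, 48.1e-9, 3.7e-8, 1)) {
    acc <- atp_accounting(Q, p)
    expect_equal(acc$n_ions, Q / p$e_charge, tolerance = 1e-13)
    expect_equal(acc$n_ATP_mol, Q / p$e_charge / (3 * p$N_A), tolerance = 1e-13)
    expect_equal(acc$E_s, p$lambda_ATP * Q / p$e_charge / (3 * p$N_A),
                 tolerance = 1e-13)
  }
  expect_equal(atp_accounting(0, p)$E_s, 0)
  expect_error(atp_accounting(-1e-9, p), class = "hh_invalid_input")
  # the pump stoichiometry generalises
  p4 <- membrane_params(na_per_atp = 4)
  expect_equal(atp_accounting(1e-6, p4)$n_ATP_mol,
               atp_accounting(1e-6, p)$n_ATP_mol * 3 / 4, tolerance = 1e-13)
})

test_that("quadrature matches closed forms for analytic integrands on the grid", {
  t <- seq(0, 30, by = 0.005)
  # constant power c over window T integrates to exactly c * T
  pw <- make_power(t, p_Na = 4)
  expect_equal(energy_consumption(pw), 4 * 30 * 1e-12, tolerance = 1e-12)
  # quadratic integrand: trapezoid error is O(dt^2)
  pw2 <- make_power(t, p_K = t^2)
  expect_equal(energy_consumption(pw2), 30^3 / 3 * 1e-12, tolerance = 1e-6)
  # stimulus term enters only when asked for
  pw3 <- make_power(t, p_Na = 1, p_stim = -0.5)
  expect_equal(energy_consumption(pw3), 30e-12, tolerance = 1e-12)
  expect_equal(energy_consumption(pw3, include_stimulus = TRUE),
               15e-12, tolerance = 1e-12)
  expect_error(energy_consumption(make_power(0, p_Na = 1)),
               class = "hh_invalid_input")
})

test_that("channel dissipation is non-negative and p_total sums its parts", {
  for (run in all_runs()) {
    pw <- run$power
    expect_true(all(pw$p_Na >= 0))
    expect_true(all(pw$p_K >= 0))
    expect_true(all(pw$p_l >= 0))
    expect_identical(pw$p_total, pw$p_Na + pw$p_K + pw$p_l + pw$p_stim)
  }
})

test_that("power peaks have the spiking and subthreshold signatures", {
  pw_supra <- supra_run()$power
  # Na+ power peak lags the K+ peak and reaches ~66% of its height
  expect_gt(pw_supra$t[which.max(pw_supra$p_Na)], pw_supra$t[which.max(pw_supra$p_K)])
  expect_gt(max(pw_supra$p_Na) / max(pw_supra$p_K), 0.60)
  expect_lt(max(pw_supra$p_Na) / max(pw_supra$p_K), 0.72)
  # subthreshold the Na+ peak power is about four times the K+ peak
  pw_sub <- sub_run()$power
  expect_gt(max(pw_sub$p_Na) / max(pw_sub$p_K), 3.5)
  expect_lt(max(pw_sub$p_Na) / max(pw_sub$p_K), 5)
})

test_that("net transmembrane charge balances the injected stimulus charge", {
  for (run in all_runs()) {
    tr <- run$trace
    if (abs(tr$V_m[nrow(tr)] - membrane_params()$V_r) > 0.5) next # not rest-returning
    qc <- net_charge(tr)
    if (qc$Q_injected == 0) {
      expect_lt(abs(qc$Q_net), 1e-9) # < 1 nC/cm2 residual at rest
    } else {
      expect_lt(abs(qc$Q_net - qc$Q_injected) / qc$Q_injected, 0.02)
    }
  }
})

test_that("zero-stimulus Na+ influx equals the resting window current", {
  tr <- rest_run()$trace
  p <- membrane_params()
  g <- hh_steady_gates(p$V_r, p)
  rest_rate <- p$g_Na * g$m^3 * g$h * (p$E_Na - p$V_r)  # uA/cm2
  baseline <- rest_rate * 30 * 1e-9                      # C/cm2 over the window
  expect_equal(na_influx_charge(tr), baseline, tolerance = 0.05)
})

test_that("efficiency arithmetic and its guards behave", {
  expect_equal(efficiency(1.879e-7, 2.468e-7), 76.13, tolerance = 1e-3)
  expect_equal(efficiency(8.75e-9, 8.31e-9), 105.3, tolerance = 1e-3)
  expect_equal(efficiency(0, 1e-9), 0)
  expect_error(efficiency(1e-9, 0), class = "hh_undefined_efficiency")
  expect_error(efficiency(1e-9, -1), class = "hh_invalid_input")
  # energy_report flags (rather than errors) an undefined efficiency
  noNa <- run_experiment(membrane_params(g_Na = 0, g_K = 0, g_l = 1),
                         stimulus_protocol(t_total = 1, dt = 0.01))
  expect_false(noNa$energy$eta_defined)
  expect_true(is.na(noNa$energy$eta))
})

test_that("per-pump-cycle energy is ~0.52 eV and scales with lambda", {
  p <- membrane_params()
  ev <- pump_cycle_energy(2.468e-7, 8.918e12, p)
  expect_equal(ev, 0.519, tolerance = 3e-3)
  # independent unit-conversion oracle: lambda per ATP in eV
  oracle <- p$lambda_ATP / p$N_A / p$e_charge
  acc <- atp_accounting(5e-7, p)
  expect_equal(pump_cycle_energy(acc$E_s, acc$n_ions, p), oracle, tolerance = 1e-12)
  # linear in lambda
  p2 <- membrane_params(lambda_ATP = 2 * p$lambda_ATP)
  acc2 <- atp_accounting(5e-7, p2)
  expect_equal(pump_cycle_energy(acc2$E_s, acc2$n_ions, p2), 2 * oracle,
               tolerance = 1e-12)
  expect_error(pump_cycle_energy(1e-7, 0), class = "hh_undefined_efficiency")
})

test_that("axon ATP estimate follows the cylinder surface", {
  n <- axon_atp_estimate(4.94e-12, diameter_mm = 1e-4, length_mm = 1)
  expect_gt(n, 8.5e6)
  expect_lt(n, 9.5e6)
  expect_equal(axon_atp_estimate(4.94e-12, length_mm = 2), 2 * n, tolerance = 1e-12)
  # with 1/N_A mol/cm2 the result is numerically the surface in cm2
  p <- membrane_params()
  expect_equal(axon_atp_estimate(1 / p$N_A, 1e-4, 1, p), 3.1416e-6, tolerance = 1e-4)
  expect_error(axon_atp_estimate(1e-12, diameter_mm = 0), class = "hh_invalid_input")
})

test_that("energy_report chains its fields exactly", {
  e <- sub_run()$energy
  p <- membrane_params()
  expect_equal(e$n_ions, e$Q_Na / p$e_charge, tolerance = 1e-12)
  expect_equal(e$n_ATP_mol, e$n_ions / (3 * p$N_A), tolerance = 1e-12)
  expect_equal(e$E_s, p$lambda_ATP * e$n_ATP_mol, tolerance = 1e-12)
  expect_equal(e$eta, 100 * e$E_c / e$E_s, tolerance = 1e-12)
  expect_true(e$E_s >= 0 && e$Q_Na >= 0)
})
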