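test_that("synchronicity attains the Cauchy-Schwarz extremes on proportional series", {
  a <- sin(seq(0, 10, by = 0.1))
  s1 <- synchronicity(a, 3 * a)
  expect_equal(s1$tau, 1, tolerance = 1e-12)
  expect_lt(s1$psi, 1e-4)
  s2 <- synchronicity(a, -a)
  expect_equal(s2$tau, -1, tolerance = 1e-12)
  expect_equal(s2$psi, 180, tolerance = 1e-6)
})

test_that("|tau| <= 1 with arccos-consistent psi on arbitrary series", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(3:200, 1)
    a <- rnorm(n)
    b <- rnorm(n)
    s <- synchronicity(a, b, t = seq(0, 1, length.out = n))
    expect_true(abs(s$tau) <= 1)
    expect_true(s$psi >= 0 && s$psi <= 180)
    expect_equal(cos(s$psi * pi / 180), s$tau, tolerance = 1e-12)
  }
})

test_that("synchronicity is scale-invariant up to the sign of the scalars", {
  set.seed(7)
  a <- rnorm(50); b <- rnorm(50); t <- seq(0, 5, length.out = 50)
  base <- synchronicity(a, b, t)$tau
  for (cd in list(c(2, 3), c(-2, 3), c(2, -3), c(-0.5, -4))) {
    got <- synchronicity(cd[1] * a, cd[2] * b, t)$tau
    expect_equal(got, sign(cd[1] * cd[2]) * base, tolerance = 1e-12)
  }
})

test_that("short-series synchronicity matches a brute-force inner-product oracle", {
  set.seed(11)
  for (n in c(3, 5, 10)) {
    a <- rnorm(n); b <- rnorm(n)
    t <- cumsum(runif(n, 0.5, 1.5)) # non-uniform grid too
    w <- trapz_weights(t)
    tau_oracle <- sum(w * a * b) / sqrt(sum(w * a^2) * sum(w * b^2))
    expect_equal(synchronicity(a, b, t)$tau, tau_oracle, tolerance = 1e-12)
  }
})

test_that("degenerate synchronicity inputs are rejected", {
  expect_error(synchronicity(rep(0, 10), rnorm(10)), class = "hh_undefined_synchrony")
  expect_error(synchronicity(1:5, 1:4), class = "hh_invalid_input")
  expect_error(synchronicity(c(1, NA, 2), c(1, 2, 3)), class = "hh_invalid_input")
})

test_that("run-level synchrony has the supra/sub signature", {
  s_supra <- supra_run()$synchrony
  s_sub <- sub_run()$synchrony
  # sign pattern: currents antiphase, powers in phase
  expect_lt(s_supra$tau_I, 0); expect_gt(s_supra$tau_E, 0)
  expect_lt(s_sub$tau_I, 0); expect_gt(s_sub$tau_E, 0)
  # current synchrony stronger when firing; power synchrony stronger subthreshold
  expect_gt(abs(s_supra$tau_I), abs(s_sub$tau_I))
  expect_gt(s_sub$tau_E, s_supra$tau_E)
})

test_that("Na/K power ratio crosses unity when firing but not subthreshold", {
  r_supra <- power_ratio_series(supra_run()$power)
  expect_gte(attr(r_supra, "n_crossings"), 2)
  r_sub <- power_ratio_series(sub_run()$power)
  expect_equal(attr(r_sub, "n_crossings"), 0)
  expect_true(all(r_sub$ratio[!is.na(r_sub$ratio)] > 1))
  # equal powers: ratio identically one, no crossings
  t <- seq(0, 1, by = 0.01)
  r_eq <- power_ratio_series(make_power(t, p_Na = 1 + t, p_K = 1 + t))
  expect_true(all(r_eq$ratio == 1))
  expect_equal(attr(r_eq, "n_crossings"), 0)
})

test_that("power fractions show the bimodal/supra and dominated/sub profiles", {
  f_sub <- power_fraction_series(sub_run()$power)
  ok <- !is.na(f_sub$frac_Na)
  expect_true(all(f_sub$frac_Na[ok] > 0.40))
  expect_true(all(f_sub$frac_K[ok] < 0.35))
  # the two ion channels jointly hold ~70% or more of the power throughout
  expect_gt(min(f_sub$frac_sum[ok]), 0.68)
  expect_equal(f_sub$frac_sum[ok], f_sub$frac_Na[ok] + f_sub$frac_K[ok],
               tolerance = 1e-12)
  # spiking: the Na+ share is bimodal — two high episodes separated by a
  # K+-dominated trough at the spike peak
  f_supra <- power_fraction_series(supra_run()$power)
  high <- which(!is.na(f_supra$frac_Na) & f_supra$frac_Na > 0.8)
  expect_gt(length(high), 0)
  gaps <- which(diff(high) > 1)
  expect_gte(length(gaps), 1)
  trough <- f_supra$frac_Na[(high[gaps[1]] + 1):(high[gaps[1] + 1] - 1)]
  expect_lt(min(trough, na.rm = TRUE), 0.35)
  # single-channel synthetic power: the Na fraction is identically 1
  t <- seq(0, 1, by = 0.01)
  f_one <- power_fraction_series(make_power(t, p_Na = exp(-t)))
  expect_true(all(f_one$frac_Na == 1, na.rm = TRUE))
})

test_that("fractions stay within [0, 1] over the channel denominator", {
  for (run in all_runs()) {
    pw <- run$power
    f <- power_fraction_series(pw)
    ok <- !is.na(f$frac_Na)
    expect_true(all(f$frac_Na[ok] >= 0 & f$frac_Na[ok] <= 1 + 1e-9))
    expect_true(all(f$frac_K[ok] >= 0 & f$frac_K[ok] <= 1 + 1e-9))
  }
})

test_that("the stimulus-power ratio separates the blasting-fuse regimes", {
  supra <- stimulus_power_ratio(supra_run()$power)
  expect_gt(attr(supra, "max_ratio"), 1e4)
  sub <- stimulus_power_ratio(sub_run()$power)
  expect_lt(attr(sub, "max_ratio"), 6)
  # identical total and stimulus power: ratio identically 1
  t <- seq(0, 1, by = 0.01)
  pw <- make_power(t, p_stim = 1 + t)
  same <- stimulus_power_ratio(pw)
  expect_true(all(same$ratio[!is.na(same$ratio)] == 1))
  expect_error(stimulus_power_ratio(make_power(t, p_Na = 1)),
               class = "hh_undefined_synchrony")
})
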