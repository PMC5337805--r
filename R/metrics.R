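## Inner-product synchrony between channel time series, and the ratio /
## fraction summaries of the power decomposition.

#' Synchronicity of two time series
#'
#' The cosine of the angle between two series under the L2 inner product,
#' \deqn{\tau = \int a b \, dt \Big/ \sqrt{\int a^2 dt \int b^2 dt},}
#' evaluated by trapezoidal quadrature on the common grid, together with the
#' phase difference `psi = arccos(tau)` in degrees. `tau = 1` means the
#' series are proportional with the same sign, `tau = -1` antiphase.
#'
#' @param a,b Equal-length numeric series on a common grid.
#' @param t Optional time grid; unit spacing is assumed when omitted.
#'
#' @return A one-row tibble with columns `tau` (in `[-1, 1]`) and `psi`
#'   (degrees, in `[0, 180]`).
#' @examples
#' synchronicity(sin(1:100 / 10), -sin(1:100 / 10)) # tau = -1, psi = 180
#' @export
synchronicity <- function(a, b, t = NULL) {
  if (!is.numeric(a) || !is.numeric(b) || length(a) != length(b) || length(a) < 2) {
    abort("a and b must be equal-length numeric series (length >= 2)",
          class = "hh_invalid_input")
  }
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    abort("series must be finite", class = "hh_invalid_input")
  }
  t <- t %||% seq_along(a)
  if (length(t) != length(a)) {
    abort("t must match the series length", class = "hh_invalid_input")
  }
  na <- trapz_grid(t, a^2)
  nb <- trapz_grid(t, b^2)
  if (na == 0 || nb == 0) {
    abort("synchronicity is undefined for an identically zero series",
          class = "hh_undefined_synchrony")
  }
  tau <- trapz_grid(t, a * b) / sqrt(na * nb)
  tau <- max(-1, min(1, tau)) # guard acos against rounding just outside [-1, 1]
  tibble(tau = tau, psi = acos(tau) * 180 / pi)
}

#' Current and power synchrony for one run
#'
#' Applies [synchronicity()] to the signed Na+/K+ current pair and to the
#' (non-negative) Na+/K+ power pair of one simulated run. Currents flow in
#' opposite directions, so `tau_I` is negative; powers are both dissipative,
#' so `tau_E` is positive.
#'
#' @param trace An `hh_trace` from [hh_simulate()].
#' @param power Optional matching [power_series()]; recomputed if omitted.
#'
#' @return A one-row tibble with columns `tau_I`, `psi_I`, `tau_E`, `psi_E`.
#' @examples
#' tr <- hh_simulate(protocol = stimulus_protocol(amplitude = 3, duration = 5))
#' synchrony_report(tr) # tau_I ~ -0.99, tau_E ~ 0.78
#' @export
synchrony_report <- function(trace, power = NULL) {
  check_trace(trace)
  pw <- power %||% power_series(trace)
  check_power(pw)
  if (nrow(pw) != nrow(trace) || !isTRUE(all.equal(pw$t, trace$t))) {
    abort("trace and power must share the same time grid",
          class = "hh_invalid_input")
  }
  sI <- synchronicity(trace$i_Na, trace$i_K, trace$t)
  sE <- synchronicity(pw$p_Na, pw$p_K, pw$t)
  tibble(tau_I = sI$tau, psi_I = sI$psi, tau_E = sE$tau, psi_E = sE$psi)
}

## Denominator floor shared by the ratio/fraction series: a sample is only
## "defined" where the denominator exceeds floor_frac of its window maximum,
## so the indeterminate 0/0 tail after recovery to rest is masked out.
mask_floor <- function(x, floor_frac) abs(x) > floor_frac * max(abs(x))

#' Na+/K+ power ratio over time
#'
#' Elementwise ratio `p_Na / p_K`, masked (`NA`) where the K+ power falls
#' below `floor_frac` of its window maximum. During an action potential the
#' ratio crosses unity several times; during subthreshold activity it stays
#' above 1 throughout. The number of crossings of the unity line over the
#' defined support is attached as attribute `n_crossings` (see
#' [unity_crossings()]).
#'
#' @param power An `hh_power` tibble from [power_series()].
#' @param floor_frac Denominator floor as a fraction of the window maximum.
#'
#' @return A tibble with columns `t` and `ratio` (NA where masked), with
#'   attribute `n_crossings`.
#' @export
power_ratio_series <- function(power, floor_frac = 1e-6) {
  check_power(power)
  defined <- mask_floor(power$p_K, floor_frac)
  ratio <- ifelse(defined, power$p_Na / power$p_K, NA_real_)
  structure(tibble(t = power$t, ratio = ratio),
            n_crossings = unity_crossings(ratio))
}

#' Count crossings of the unity line
#'
#' Number of sign changes of `x - 1` between consecutive defined (non-`NA`)
#' samples of a series. Samples exactly equal to 1 do not count as crossings
#' on their own.
#'
#' @param x Numeric series, possibly with `NA` gaps.
#' @return Integer crossing count.
#' @export
unity_crossings <- function(x) {
  s <- sign(x[!is.na(x)] - 1)
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(diff(s) != 0)
}

#' Channel shares of total power over time
#'
#' Elementwise fractions of the Na+ and K+ dissipation over the total power
#' and their sum, masked where the denominator falls below `floor_frac` of
#' its window maximum (after recovery to rest the total is too small for the
#' fractions to be meaningful). By default the denominator is the channel
#' dissipation `p_Na + p_K + p_l`, the same "total power" the energy
#' consumption integrates, so the fractions are proper shares in `[0, 1]`;
#' `denominator = "full"` divides by `p_total` including the (possibly
#' negative) electrode term instead. With a spike the Na+ share is bimodal,
#' peaking on the upstroke and again during recovery with the K+ channel
#' taking over in between; subthreshold, the two ion channels jointly hold
#' about 70% or more of the power throughout.
#'
#' @inheritParams power_ratio_series
#' @param denominator `"channel"` (default) for `p_Na + p_K + p_l`, or
#'   `"full"` for `p_total` including the stimulus term.
#' @return A tibble with columns `t`, `frac_Na`, `frac_K`, `frac_sum`
#'   (NA where masked).
#' @export
power_fraction_series <- function(power, floor_frac = 1e-6,
                                  denominator = c("channel", "full")) {
  check_power(power)
  denominator <- match.arg(denominator)
  den <- if (denominator == "channel") {
    power$p_Na + power$p_K + power$p_l
  } else {
    power$p_total
  }
  defined <- mask_floor(den, floor_frac)
  frac_Na <- ifelse(defined, power$p_Na / den, NA_real_)
  frac_K <- ifelse(defined, power$p_K / den, NA_real_)
  tibble(t = power$t, frac_Na = frac_Na, frac_K = frac_K,
         frac_sum = frac_Na + frac_K)
}

#' Total-over-stimulus power ratio over time
#'
#' The magnitude ratio `|p_total| / |p_stim|`, evaluated only on the support
#' where the stimulus power exceeds `floor_frac` of its window maximum. A
#' large maximum (hundreds of thousands when a spike fires) is the
#' "blasting fuse" effect: the stimulus energy is negligible relative to
#' the response it triggers. The maximum over the support is attached as
#' attribute `max_ratio`.
#'
#' @inheritParams power_ratio_series
#' @return A tibble with columns `t` and `ratio` (NA off the stimulus
#'   support), with attribute `max_ratio`.
#' @export
stimulus_power_ratio <- function(power, floor_frac = 1e-6) {
  check_power(power)
  if (all(power$p_stim == 0)) {
    abort("stimulus power is identically zero; ratio undefined",
          class = "hh_undefined_synchrony")
  }
  defined <- mask_floor(power$p_stim, floor_frac)
  ratio <- ifelse(defined, abs(power$p_total) / abs(power$p_stim), NA_real_)
  structure(tibble(t = power$t, ratio = ratio),
            max_ratio = max(ratio, na.rm = TRUE))
}
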