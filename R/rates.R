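## Gating kinetics. All rate functions are written in the depolarisation
## coordinate u = V_m - V_r (mV, positive = depolarised), the convention in
## which the classical squid-axon fits were made. The rational forms
## x/(exp(x)-1) have removable singularities at x = 0; they are evaluated by
## the series limit 1 - x/2 inside |x| < 1e-7.

exprel_inv <- function(x) {
  # x / (exp(x) - 1), analytic at 0
  ifelse(abs(x) < 1e-7, 1 - x / 2, x / expm1(x))
}

rate_fns <- function(u) {
  list(
    alpha_n = 0.1 * exprel_inv((10 - u) / 10),
    beta_n  = 0.125 * exp(-u / 80),
    alpha_m = exprel_inv((25 - u) / 10),
    beta_m  = 4 * exp(-u / 18),
    alpha_h = 0.07 * exp(-u / 20),
    beta_h  = 1 / (exp((30 - u) / 10) + 1)
  )
}

#' Voltage-dependent gating rate constants
#'
#' Evaluates the six Hodgkin-Huxley opening/closing rates for the K+
#' activation gate n, Na+ activation gate m and Na+ inactivation gate h at
#' one or more membrane potentials. Rates are functions of the
#' depolarisation `u = V_m - V_r`; the removable singularities of the
#' rational alpha_n and alpha_m forms (at u = 10 and u = 25 mV) are handled
#' by their analytic limits.
#'
#' @param V_m Membrane potential(s) (mV); must be finite.
#' @param params A [membrane_params()] object (supplies `V_r`).
#'
#' @return A tibble with columns `V_m`, `alpha_n`, `beta_n`, `alpha_m`,
#'   `beta_m`, `alpha_h`, `beta_h` (all in 1/ms), one row per input voltage.
#' @examples
#' hh_rate_constants(c(-67.3, -47.3), membrane_params())
#' @export
hh_rate_constants <- function(V_m, params = membrane_params()) {
  check_params(params)
  if (!is.numeric(V_m) || length(V_m) == 0 || any(!is.finite(V_m))) {
    abort("V_m must be finite numeric", class = "hh_invalid_input")
  }
  r <- rate_fns(V_m - params$V_r)
  tibble(V_m = V_m, !!!r)
}

#' Steady-state gating variables
#'
#' The stationary point `x_inf = alpha_x / (alpha_x + beta_x)` of each gating
#' ODE at a clamped membrane potential. At `V_m = V_r` this is the initial
#' condition used by [hh_simulate()].
#'
#' @inheritParams hh_rate_constants
#' @return A tibble with columns `V_m`, `n`, `m`, `h`; each gating value lies
#'   in (0, 1).
#' @examples
#' hh_steady_gates(-67.3) # classical resting values n ~ 0.32, m ~ 0.05, h ~ 0.60
#' @export
hh_steady_gates <- function(V_m, params = membrane_params()) {
  r <- hh_rate_constants(V_m, params)
  tibble(
    V_m = r$V_m,
    n = r$alpha_n / (r$alpha_n + r$beta_n),
    m = r$alpha_m / (r$alpha_m + r$beta_m),
    h = r$alpha_h / (r$alpha_h + r$beta_h)
  )
}
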