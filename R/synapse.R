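## Energy-form Hebbian rule: the instantaneous weight-change rate between
## two neurons is a windowed correlation of their power traces,
##   k dw_ji/dt = int_0^inf [ P_i(tau) H(tau) P_j(t - tau)
##                           + P_i(t - tau) H(-tau) P_j(tau) ] dtau,
## truncated at a finite support and evaluated by trapezoidal quadrature on
## the shared trace grid.

#' Configuration for the energy-form Hebbian rule
#'
#' @param k Rate constant dividing the correlation integral; the rule is
#'   reported per unit `k` by default.
#' @param tau_H Decay time constant of the default exponential window (ms).
#' @param support Truncation half-width of the integral (ms); the window
#'   must have decayed essentially to zero within it.
#' @param asymmetry Weight of the negative-lag branch of the default window:
#'   `H(tau) = exp(-|tau|/tau_H)` for `tau >= 0` and
#'   `-asymmetry * exp(-|tau|/tau_H)` for `tau < 0` (a spike-timing-style
#'   sign split; set `asymmetry = -1` for a symmetric window).
#' @param window Optional window function `H(tau)` overriding the default;
#'   must return finite values on `[-support, support]`.
#'
#' @return An object of class `hebbian_config`.
#' @examples
#' hebbian_config(tau_H = 5, support = 25)
#' @export
hebbian_config <- function(k = 1, tau_H = 5, support = 25, asymmetry = 1,
                           window = NULL) {
  ok <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  if (!ok(k) || k == 0) abort("k must be a nonzero finite scalar", class = "hh_invalid_input")
  if (!ok(tau_H) || tau_H <= 0) abort("tau_H must be > 0", class = "hh_invalid_input")
  if (!ok(support) || support <= 0) abort("support must be > 0", class = "hh_invalid_input")
  if (!ok(asymmetry)) abort("asymmetry must be a finite scalar", class = "hh_invalid_input")
  if (is.null(window)) {
    window <- function(tau) {
      ifelse(tau >= 0, 1, -asymmetry) * exp(-abs(tau) / tau_H)
    }
  }
  if (!is.function(window)) abort("window must be a function", class = "hh_invalid_input")
  probe <- window(c(-support, 0, support))
  if (any(!is.finite(probe))) {
    abort("window must be finite on [-support, support]", class = "hh_invalid_input")
  }
  structure(list(k = k, tau_H = tau_H, support = support,
                 asymmetry = asymmetry, window = window),
            class = "hebbian_config")
}

hebbian_series <- function(x, col) {
  if (is.data.frame(x)) {
    if (!all(c("t", col) %in% names(x))) {
      abort(sprintf("power input must contain columns `t` and `%s`", col),
            class = "hh_invalid_input")
    }
    list(t = x$t, p = x[[col]])
  } else {
    abort("power inputs must be data frames with a `t` column",
          class = "hh_invalid_input")
  }
}

#' Hebbian weight-change rate from two power traces
#'
#' Evaluates the energy-form Hebbian rule at time `at`: a truncated windowed
#' correlation of the two neurons' power series, scaled by `1/k`. Both
#' series must live on the same uniform time grid, which must cover
#' `[0, support]` and `[at - support, at]` (the lags the integral touches).
#'
#' @param power_i,power_j Data frames with a `t` column and the power column
#'   named by `col` (e.g. an [power_series()] result, or any power series
#'   on a shared grid).
#' @param at Evaluation time `t` (ms); must lie on the grid.
#' @param config A [hebbian_config()].
#' @param col Name of the power column to use (default `"p_total"`; the rule
#'   accepts any power series, total or channel-restricted).
#'
#' @return The scalar rate `dw_ji/dt` (power-squared times time per `k`).
#' @examples
#' g <- tibble::tibble(t = seq(0, 30, by = 0.1), p_total = exp(-(seq(0, 30, by = 0.1) - 10)^2))
#' hebbian_weight_rate(g, g, at = 15, config = hebbian_config(support = 10))
#' @export
hebbian_weight_rate <- function(power_i, power_j, at,
                                config = hebbian_config(), col = "p_total") {
  if (!inherits(config, "hebbian_config")) {
    abort("`config` must be a hebbian_config", class = "hh_invalid_input")
  }
  si <- hebbian_series(power_i, col)
  sj <- hebbian_series(power_j, col)
  if (length(si$t) != length(sj$t) || !isTRUE(all.equal(si$t, sj$t))) {
    abort("power_i and power_j must share the same time grid",
          class = "hh_invalid_input")
  }
  t <- si$t
  if (length(t) < 2) abort("grid too short", class = "hh_invalid_input")
  dt <- t[2] - t[1]
  if (max(abs(diff(t) - dt)) > 1e-9 * max(dt, 1)) {
    abort("time grid must be uniform", class = "hh_invalid_input")
  }
  if (!is.numeric(at) || length(at) != 1 || !is.finite(at)) {
    abort("`at` must be a finite scalar time", class = "hh_invalid_input")
  }

  support <- config$support
  t_min <- t[1]; t_max <- t[length(t)]
  need_lo <- min(0, at - support)
  need_hi <- max(support, at)
  if (need_lo < t_min - 1e-9 || need_hi > t_max + 1e-9) {
    abort(sprintf(
      "grid [%g, %g] ms does not cover the required span [%g, %g] ms for t = %g, support = %g",
      t_min, t_max, need_lo, need_hi, at, support), class = "hh_invalid_input")
  }

  idx_of <- function(times) {
    i <- round((times - t_min) / dt) + 1
    if (max(abs(times - t[i])) > 1e-6 * max(dt, 1)) {
      abort("evaluation times must lie on the grid (is `at` a grid point?)",
            class = "hh_invalid_input")
    }
    i
  }
  tau <- seq(0, floor(support / dt + 1e-9)) * dt
  Pi_tau <- si$p[idx_of(tau)]
  Pj_tau <- sj$p[idx_of(tau)]
  Pi_lag <- si$p[idx_of(at - tau)]
  Pj_lag <- sj$p[idx_of(at - tau)]
  integrand <- Pi_tau * config$window(tau) * Pj_lag +
    Pi_lag * config$window(-tau) * Pj_tau
  trapz_grid(tau, integrand) / config$k
}

#' Hebbian rate series over a trace
#'
#' Convenience wrapper evaluating [hebbian_weight_rate()] at every grid time
#' for which the required span is covered.
#'
#' @inheritParams hebbian_weight_rate
#' @return A tibble with columns `t` and `rate`.
#' @export
hebbian_rate_series <- function(power_i, power_j,
                                config = hebbian_config(), col = "p_total") {
  si <- hebbian_series(power_i, col)
  t <- si$t
  ok <- t - config$support >= t[1] - 1e-9 & t <= t[length(t)] + 1e-9 &
    config$support <= t[length(t)] + 1e-9
  ts <- t[ok]
  tibble(t = ts,
         rate = map_dbl(ts, function(tt) {
           hebbian_weight_rate(power_i, power_j, tt, config, col)
         }))
}
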