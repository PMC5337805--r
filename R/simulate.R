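#' Simulate a Hodgkin-Huxley neuron under a step-current stimulus
#'
#' Integrates the four-variable membrane model
#' \deqn{C_m dV_m/dt = g_l(E_l - V_m) + g_{Na} m^3 h (E_{Na} - V_m) +
#'       g_K n^4 (E_K - V_m) + I(t)}
#' with the usual first-order gating kinetics, using classical fixed-step
#' fourth-order Runge-Kutta on the grid `seq(0, t_total, by = dt)`
#' (via [deSolve::ode()] with `method = "rk4"`). The run starts from rest:
#' `V(0) = V_r`, gates at their steady state for `V_r`.
#'
#' Channel currents are stored in the driving-force convention
#' `i_x = g_x (E_x - V_m)`, i.e. positive means inward for the Na+ channel
#' near rest. Outward-positive views for presentation are obtained by
#' negation at plot time, never in the stored trace.
#'
#' @param params A [membrane_params()] object.
#' @param protocol A [stimulus_protocol()] object.
#'
#' @return A tibble of class `hh_trace` with columns `t` (ms), `V_m` (mV),
#'   gating variables `n`, `m`, `h`, and current densities `i_Na`, `i_K`,
#'   `i_l`, `i_stim` (uA/cm2). The parameter and protocol objects ride along
#'   as attributes `membrane` and `protocol`.
#' @examples
#' tr <- hh_simulate(protocol = stimulus_protocol(amplitude = 3, duration = 5))
#' max(tr$V_m) # spike overshoot well above 0 mV
#' @export
hh_simulate <- function(params = membrane_params(),
                        protocol = stimulus_protocol()) {
  check_params(params)
  check_protocol(protocol)

  t_grid <- seq(0, protocol$t_total, by = protocol$dt)
  stim_on <- function(t) {
    as.numeric(t >= protocol$onset & t < protocol$onset + protocol$duration)
  }

  deriv <- function(t, y, parms) {
    V <- y[[1]]; n <- y[[2]]; m <- y[[3]]; h <- y[[4]]
    r <- rate_fns(V - params$V_r)
    I <- protocol$amplitude * stim_on(t)
    i_Na <- params$g_Na * m^3 * h * (params$E_Na - V)
    i_K  <- params$g_K * n^4 * (params$E_K - V)
    i_l  <- params$g_l * (params$E_l - V)
    list(c(
      (i_l + i_Na + i_K + I) / params$C_m,
      r$alpha_n * (1 - n) - r$beta_n * n,
      r$alpha_m * (1 - m) - r$beta_m * m,
      r$alpha_h * (1 - h) - r$beta_h * h
    ))
  }

  g0 <- hh_steady_gates(params$V_r, params)
  y0 <- c(V = params$V_r, n = g0$n, m = g0$m, h = g0$h)
  out <- deSolve::ode(y = y0, times = t_grid, func = deriv, parms = NULL,
                      method = "rk4")

  if (any(!is.finite(out))) {
    bad <- which(apply(out, 1, function(row) any(!is.finite(row))))[1]
    abort(sprintf("integration became non-finite at t = %g ms", t_grid[bad]),
          class = "hh_integration_error")
  }

  V <- out[, "V"]; n <- out[, "n"]; m <- out[, "m"]; h <- out[, "h"]
  trace <- tibble(
    t = t_grid,
    V_m = V,
    n = n, m = m, h = h,
    i_Na = params$g_Na * m^3 * h * (params$E_Na - V),
    i_K = params$g_K * n^4 * (params$E_K - V),
    i_l = params$g_l * (params$E_l - V),
    i_stim = protocol$amplitude * stim_on(t_grid)
  )
  new_hh_trace(trace, params, protocol)
}

new_hh_trace <- function(df, params, protocol) {
  structure(df,
            membrane = params,
            protocol = protocol,
            class = c("hh_trace", class(tibble())))
}

trace_cols <- c("t", "V_m", "n", "m", "h", "i_Na", "i_K", "i_l", "i_stim")

check_trace <- function(trace) {
  if (!is.data.frame(trace) || !all(trace_cols %in% names(trace))) {
    abort(paste0("`trace` must contain columns ",
                 paste(trace_cols, collapse = ", ")),
          class = "hh_invalid_input")
  }
  if (nrow(trace) < 2) {
    abort("`trace` must contain at least two samples", class = "hh_invalid_input")
  }
  trace
}

trace_membrane <- function(trace, params = NULL) {
  p <- params %||% attr(trace, "membrane")
  if (is.null(p)) {
    abort("trace carries no `membrane` attribute; pass `params` explicitly",
          class = "hh_invalid_input")
  }
  check_params(p)
}

trace_protocol <- function(trace) {
  p <- attr(trace, "protocol")
  if (is.null(p)) {
    abort("trace carries no `protocol` attribute", class = "hh_invalid_input")
  }
  check_protocol(p)
}
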