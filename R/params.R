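#' Membrane and pump parameters
#'
#' Bundles the electrophysiological constants of the Hodgkin-Huxley membrane
#' together with the physical constants needed for ATP accounting. Defaults
#' are the classical squid-axon conductances with Nernst potentials
#' `E_Na = 50`, `E_K = -80`, `E_l = -56` mV and a resting potential of
#' -67.3 mV, for which the resting state is (very nearly) an equilibrium of
#' the full system.
#'
#' @param C_m Membrane capacitance (uF/cm2).
#' @param g_Na,g_K,g_l Maximal Na+, K+ and leak conductances (mS/cm2).
#' @param E_Na,E_K,E_l Reversal (Nernst) potentials (mV); must satisfy
#'   `E_K < E_l < E_Na`.
#' @param V_r Resting membrane potential (mV); also the origin of the
#'   depolarisation axis used by the gating rate functions.
#' @param lambda_ATP Free energy released per mole of ATP hydrolysed (J/mol).
#'   50 kJ/mol by default; physiological estimates range 46-62 kJ/mol.
#' @param e_charge Elementary charge (C).
#' @param N_A Avogadro constant (1/mol).
#' @param na_per_atp Na+ ions extruded by the Na+/K+ pump per ATP consumed
#'   (3 for the physiological 3 Na+ out / 2 K+ in stoichiometry).
#'
#' @return An object of class `membrane_params` (a validated named list).
#' @examples
#' membrane_params()
#' membrane_params(lambda_ATP = 62e3) # upper end of the ATP free-energy range
#' @export
membrane_params <- function(C_m = 1,
                            g_Na = 120, g_K = 36, g_l = 0.3,
                            E_Na = 50, E_K = -80, E_l = -56,
                            V_r = -67.3,
                            lambda_ATP = 50e3,
                            e_charge = 1.602176634e-19,
                            N_A = 6.02214076e23,
                            na_per_atp = 3) {
  p <- list(C_m = C_m, g_Na = g_Na, g_K = g_K, g_l = g_l,
            E_Na = E_Na, E_K = E_K, E_l = E_l, V_r = V_r,
            lambda_ATP = lambda_ATP, e_charge = e_charge, N_A = N_A,
            na_per_atp = na_per_atp)
  bad <- names(p)[!vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x), logical(1))]
  if (length(bad) > 0) {
    abort(paste0("membrane parameter(s) not finite scalar numeric: ",
                 paste(bad, collapse = ", ")), class = "hh_invalid_input")
  }
  if (p$C_m <= 0) abort("C_m must be > 0", class = "hh_invalid_input")
  if (p$g_Na < 0 || p$g_K < 0 || p$g_l < 0) {
    abort("conductances g_Na, g_K, g_l must be >= 0", class = "hh_invalid_input")
  }
  if (p$lambda_ATP <= 0) abort("lambda_ATP must be > 0", class = "hh_invalid_input")
  if (p$e_charge <= 0 || p$N_A <= 0 || p$na_per_atp <= 0) {
    abort("e_charge, N_A and na_per_atp must be > 0", class = "hh_invalid_input")
  }
  if (!(p$E_K < p$E_l && p$E_l < p$E_Na)) {
    abort("reversal potentials must be ordered E_K < E_l < E_Na",
          class = "hh_invalid_input")
  }
  structure(p, class = "membrane_params")
}

#' @export
print.membrane_params <- function(x, ...) {
  cat("<membrane_params>\n")
  cat(sprintf("  C_m = %g uF/cm2; g_Na/g_K/g_l = %g/%g/%g mS/cm2\n",
              x$C_m, x$g_Na, x$g_K, x$g_l))
  cat(sprintf("  E_Na/E_K/E_l = %g/%g/%g mV; V_r = %g mV\n",
              x$E_Na, x$E_K, x$E_l, x$V_r))
  cat(sprintf("  lambda_ATP = %g J/mol; %g Na+ per ATP\n",
              x$lambda_ATP, x$na_per_atp))
  invisible(x)
}

#' Step-current stimulus protocol
#'
#' A rectangular current step of given amplitude and duration, embedded in a
#' simulation window `[0, t_total]` integrated at fixed step `dt`. The
#' default window of 30 ms is long enough for all supra- and subthreshold
#' transients of the default membrane to decay back to rest.
#'
#' @param amplitude Step current density (uA/cm2); may be 0.
#' @param onset Stimulus onset time (ms).
#' @param duration Stimulus duration (ms); current is on for
#'   `onset <= t < onset + duration`.
#' @param t_total Total simulated window (ms); must cover the stimulus.
#' @param dt Fixed integration step (ms).
#'
#' @return An object of class `stimulus_protocol`.
#' @examples
#' stimulus_protocol(amplitude = 3, duration = 5)   # fires one spike
#' stimulus_protocol(amplitude = 2.5, duration = 3) # subthreshold
#' @export
stimulus_protocol <- function(amplitude = 0, onset = 0, duration = 0,
                              t_total = 30, dt = 0.005) {
  p <- list(amplitude = amplitude, onset = onset, duration = duration,
            t_total = t_total, dt = dt)
  bad <- names(p)[!vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x), logical(1))]
  if (length(bad) > 0) {
    abort(paste0("protocol field(s) not finite scalar numeric: ",
                 paste(bad, collapse = ", ")), class = "hh_invalid_input")
  }
  if (p$dt <= 0) abort("dt must be > 0", class = "hh_invalid_input")
  if (p$onset < 0 || p$duration < 0) {
    abort("onset and duration must be >= 0", class = "hh_invalid_input")
  }
  if (p$t_total < p$onset + p$duration) {
    abort("t_total must be >= onset + duration", class = "hh_invalid_input")
  }
  structure(p, class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf("<stimulus_protocol> %g uA/cm2 for %g ms from t = %g; window %g ms, dt = %g ms\n",
              x$amplitude, x$duration, x$onset, x$t_total, x$dt))
  invisible(x)
}

check_params <- function(params) {
  if (!inherits(params, "membrane_params")) {
    abort("`params` must be created by membrane_params()", class = "hh_invalid_input")
  }
  params
}

check_protocol <- function(protocol) {
  if (!inherits(protocol, "stimulus_protocol")) {
    abort("`protocol` must be created by stimulus_protocol()", class = "hh_invalid_input")
  }
  protocol
}
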