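## Energy bookkeeping: ATP supply by Na+ ion counting, consumption as the
## power integral, and the derived per-pump-cycle and per-axon quantities.

trapz_grid <- function(t, y) pracma::trapz(t, y)

#' Instantaneous channel power dissipation
#'
#' Evaluates, on the trace grid, the power dissipated in each channel branch
#' (`p_x = i_x (E_x - V_m) = g_x (E_x - V_m)^2 >= 0`) and the power delivered
#' by the stimulus electrode (`p_stim = V_m I`, which is negative while the
#' membrane is below 0 mV). `p_total` is the sum of all four terms, the time
#' derivative of the neuron's stored electric energy.
#'
#' @param trace An `hh_trace` from [hh_simulate()].
#' @param params Optional [membrane_params()]; defaults to the trace's own.
#'
#' @return A tibble of class `hh_power` with columns `t` (ms) and `p_Na`,
#'   `p_K`, `p_l`, `p_stim`, `p_total` (nW/cm2), carrying the same
#'   `membrane`/`protocol` attributes as the trace.
#' @examples
#' tr <- hh_simulate(protocol = stimulus_protocol(amplitude = 3, duration = 5))
#' pw <- power_series(tr)
#' max(pw$p_Na) / max(pw$p_K) # Na+ peak power ~ 66% of K+ peak when spiking
#' @export
power_series <- function(trace, params = NULL) {
  check_trace(trace)
  p <- trace_membrane(trace, params)
  pw <- tibble(
    t = trace$t,
    p_Na = trace$i_Na * (p$E_Na - trace$V_m),
    p_K = trace$i_K * (p$E_K - trace$V_m),
    p_l = trace$i_l * (p$E_l - trace$V_m),
    p_stim = trace$V_m * trace$i_stim
  )
  pw$p_total <- pw$p_Na + pw$p_K + pw$p_l + pw$p_stim
  structure(pw,
            membrane = p,
            protocol = attr(trace, "protocol"),
            class = c("hh_power", class(tibble())))
}

power_cols <- c("t", "p_Na", "p_K", "p_l", "p_stim", "p_total")

check_power <- function(power) {
  if (!is.data.frame(power) || !all(power_cols %in% names(power))) {
    abort(paste0("`power` must contain columns ",
                 paste(power_cols, collapse = ", ")),
          class = "hh_invalid_input")
  }
  if (nrow(power) < 2) {
    abort("`power` must contain at least two samples", class = "hh_invalid_input")
  }
  power
}

#' Na+ influx charge
#'
#' Trapezoidal time integral of the inward Na+ current over the full trace
#' window. This is the charge the Na+/K+ pump must move back out to restore
#' the resting state, and hence the basis of the ATP supply estimate. Samples
#' where the Na+ driving force would reverse (`V_m > E_Na`, which does not
#' occur in this model) are clipped at zero with a warning.
#'
#' @inheritParams power_series
#' @return Charge in C/cm2 (a non-negative scalar).
#' @examples
#' tr <- hh_simulate(protocol = stimulus_protocol(amplitude = 3, duration = 5))
#' na_influx_charge(tr) * 1e6 # ~ 1.43 uC/cm2 for one action potential
#' @export
na_influx_charge <- function(trace) {
  check_trace(trace)
  i_in <- trace$i_Na
  if (any(i_in < 0)) {
    warn(sprintf("%d sample(s) with outward Na+ current clipped to 0 in the influx integral",
                 sum(i_in < 0)))
    i_in <- pmax(i_in, 0)
  }
  trapz_grid(trace$t, i_in) * .nC_to_C
}

#' ATP accounting from Na+ influx charge
#'
#' Converts an integrated Na+ influx charge into an ion count, moles of ATP
#' the pump consumes to extrude those ions (`na_per_atp` ions per ATP), and
#' the metabolic energy supply `E_s = lambda_ATP * n_ATP_mol`.
#'
#' @param Q_Na Na+ influx charge (C/cm2, >= 0).
#' @param params A [membrane_params()] object (supplies `e_charge`, `N_A`,
#'   `na_per_atp`, `lambda_ATP`).
#'
#' @return A one-row tibble with columns `Q_Na` (C/cm2), `n_ions` (1/cm2),
#'   `n_ATP_mol` (mol/cm2) and `E_s` (J/cm2).
#' @examples
#' atp_accounting(1.429e-6) # the single-spike ion and ATP budget
#' @export
atp_accounting <- function(Q_Na, params = membrane_params()) {
  check_params(params)
  if (!is.numeric(Q_Na) || length(Q_Na) != 1 || !is.finite(Q_Na) || Q_Na < 0) {
    abort("Q_Na must be a finite scalar >= 0", class = "hh_invalid_input")
  }
  n_ions <- Q_Na / params$e_charge
  n_ATP_mol <- n_ions / (params$na_per_atp * params$N_A)
  tibble(Q_Na = Q_Na, n_ions = n_ions, n_ATP_mol = n_ATP_mol,
         E_s = params$lambda_ATP * n_ATP_mol)
}

#' Electric energy consumption
#'
#' Trapezoidal time integral of the dissipated power over the full window,
#' converted to J/cm2. By default the integrand is the channel dissipation
#' `p_Na + p_K + p_l`: the joule heat produced in the three resistive
#' branches, which is what the potential energy stored by the pump pays for.
#' Set `include_stimulus = TRUE` to add the electrode work term `V_m I` and
#' integrate `p_total` instead; for the step stimuli used here that term is
#' a small negative correction (the electrode holds the membrane below
#' 0 mV while injecting positive current).
#'
#' @param power An `hh_power` tibble from [power_series()].
#' @param include_stimulus Include the `p_stim` electrode term? Default
#'   `FALSE` (channel dissipation only).
#'
#' @return Energy in J/cm2 (scalar).
#' @examples
#' tr <- hh_simulate(protocol = stimulus_protocol(amplitude = 3, duration = 5))
#' energy_consumption(power_series(tr)) # ~ 1.88e-7 J/cm2 per action potential
#' @export
energy_consumption <- function(power, include_stimulus = FALSE) {
  check_power(power)
  integrand <- power$p_Na + power$p_K + power$p_l
  if (include_stimulus) integrand <- integrand + power$p_stim
  trapz_grid(power$t, integrand) * .nWms_to_J
}

#' Energy efficiency
#'
#' The percentage of the ATP energy supply that is dissipated as electric
#' energy over the same window, `eta = 100 * E_c / E_s`. Values above 100%
#' (typical of subthreshold activity) mean the channels dissipate more
#' energy than the concurrent Na+ influx obliges the pump to replace — an
#' energy overdraft repaid later at rest.
#'
#' @param E_c Energy consumption (J/cm2).
#' @param E_s Energy supply (J/cm2); must be > 0.
#'
#' @return Efficiency in percent (scalar).
#' @examples
#' efficiency(1.879e-7, 2.468e-7) # ~ 76% during an action potential
#' @export
efficiency <- function(E_c, E_s) {
  if (!is.numeric(E_c) || !is.numeric(E_s) || length(E_c) != 1 ||
      length(E_s) != 1 || !is.finite(E_c) || !is.finite(E_s) || E_s < 0) {
    abort("E_c and E_s must be finite scalars with E_s >= 0",
          class = "hh_invalid_input")
  }
  if (E_s == 0) {
    abort("efficiency is undefined for zero energy supply",
          class = "hh_undefined_efficiency")
  }
  100 * E_c / E_s
}

#' Net transmembrane charge balance
#'
#' Integrates the net outward ionic current `-(i_Na + i_K + i_l)` over the
#' window and compares it with the charge injected by the stimulus
#' (`amplitude * duration`). For any protocol whose final state returns to
#' rest the two agree closely: the ions that cross the membrane during the
#' response exactly neutralise the injected stimulus charge.
#'
#' @inheritParams power_series
#' @return A one-row tibble with columns `Q_net` and `Q_injected` (C/cm2).
#' @examples
#' tr <- hh_simulate(protocol = stimulus_protocol(amplitude = 3, duration = 5))
#' net_charge(tr) * 1e9 # both ~ 15 nC/cm2
#' @export
net_charge <- function(trace) {
  check_trace(trace)
  proto <- trace_protocol(trace)
  Q_net <- trapz_grid(trace$t, -(trace$i_Na + trace$i_K + trace$i_l)) * .nC_to_C
  tibble(Q_net = Q_net,
         Q_injected = proto$amplitude * proto$duration * .nC_to_C)
}

#' Energy per Na+/K+ pump cycle
#'
#' The energy attributed to one pump cycle (extrusion of `na_per_atp` Na+
#' ions, i.e. hydrolysis of one ATP), obtained from a supply estimate and
#' the matching ion count, expressed in electron-volts.
#'
#' @param E_s Energy supply (J/cm2).
#' @param n_ions Na+ ion count over the same window (1/cm2); must be > 0.
#' @param params A [membrane_params()] object.
#'
#' @return Energy per pump cycle in eV (scalar).
#' @examples
#' pump_cycle_energy(2.468e-7, 8.918e12) # ~ 0.52 eV per 3 Na+ extruded
#' @export
pump_cycle_energy <- function(E_s, n_ions, params = membrane_params()) {
  check_params(params)
  if (!is.numeric(n_ions) || length(n_ions) != 1 || !is.finite(n_ions) || n_ions < 0) {
    abort("n_ions must be a finite scalar >= 0", class = "hh_invalid_input")
  }
  if (n_ions == 0) {
    abort("pump-cycle energy is undefined for zero ion count",
          class = "hh_undefined_efficiency")
  }
  (E_s / (n_ions / params$na_per_atp)) / params$e_charge
}

#' ATP molecules to propagate a spike along an axon
#'
#' Scales a per-area ATP consumption (mol/cm2, as produced by
#' [atp_accounting()] for one action potential) by the lateral surface
#' `pi * d * L` of a cylindrical axon, returning the absolute number of ATP
#' molecules spent to carry the spike down the axon.
#'
#' @param n_ATP_mol_per_cm2 ATP consumed per unit membrane area (mol/cm2).
#' @param diameter_mm Axon diameter (mm); typical fibre ~ 1e-4 mm.
#' @param length_mm Axon length (mm).
#' @param params A [membrane_params()] object (supplies `N_A`).
#'
#' @return Number of ATP molecules (scalar).
#' @examples
#' axon_atp_estimate(4.94e-12) # ~ 9e6 molecules for a 1 mm axon
#' @export
axon_atp_estimate <- function(n_ATP_mol_per_cm2, diameter_mm = 1e-4,
                              length_mm = 1, params = membrane_params()) {
  check_params(params)
  ok <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  if (!ok(n_ATP_mol_per_cm2) || n_ATP_mol_per_cm2 < 0) {
    abort("n_ATP_mol_per_cm2 must be a finite scalar >= 0", class = "hh_invalid_input")
  }
  if (!ok(diameter_mm) || !ok(length_mm) || diameter_mm <= 0 || length_mm <= 0) {
    abort("axon geometry must be positive", class = "hh_invalid_input")
  }
  surface_cm2 <- pi * (diameter_mm * 0.1) * (length_mm * 0.1)
  surface_cm2 * n_ATP_mol_per_cm2 * params$N_A
}

#' Full energy report for one simulated run
#'
#' Chains the energetics operations on one trace: Na+ influx charge, ion and
#' ATP counts, energy supply and consumption, efficiency, net charge balance
#' and the spike flag.
#'
#' @inheritParams power_series
#' @param power Optional precomputed [power_series()] for the trace.
#' @param include_stimulus Passed to [energy_consumption()].
#' @param spike_threshold Voltage threshold (mV) passed to [detect_spikes()].
#'
#' @return A one-row tibble with columns `Q_Na`, `n_ions`, `n_ATP_mol`,
#'   `E_s`, `E_c` (SI units per cm2), `eta` (%; `NA` when the supply is zero
#'   and efficiency is undefined), `eta_defined`, `Q_net`, `Q_injected`
#'   (C/cm2) and `spiked`.
#' @examples
#' tr <- hh_simulate(protocol = stimulus_protocol(amplitude = 2.5, duration = 3))
#' energy_report(tr)$eta # > 100%: subthreshold energy overdraft
#' @export
energy_report <- function(trace, power = NULL, params = NULL,
                          include_stimulus = FALSE, spike_threshold = 0) {
  check_trace(trace)
  p <- trace_membrane(trace, params)
  pw <- power %||% power_series(trace, p)
  atp <- atp_accounting(na_influx_charge(trace), p)
  E_c <- energy_consumption(pw, include_stimulus = include_stimulus)
  eta <- if (atp$E_s > 0) 100 * E_c / atp$E_s else NA_real_
  qc <- net_charge(trace)
  spikes <- detect_spikes(trace, threshold = spike_threshold)
  tibble(
    Q_Na = atp$Q_Na, n_ions = atp$n_ions, n_ATP_mol = atp$n_ATP_mol,
    E_s = atp$E_s, E_c = E_c,
    eta = eta, eta_defined = atp$E_s > 0,
    Q_net = qc$Q_net, Q_injected = qc$Q_injected,
    spiked = nrow(spikes) > 0
  )
}
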