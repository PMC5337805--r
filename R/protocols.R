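#' Detect action potentials in a voltage trace
#'
#' An action potential is counted at each upward crossing of a fixed voltage
#' threshold (default 0 mV absolute), which cleanly separates full-height
#' spikes (overshooting ~ +40 mV) from subthreshold responses of a few mV.
#' Crossing times are linearly interpolated between samples.
#'
#' @param trace An `hh_trace` from [hh_simulate()].
#' @param threshold Crossing threshold (mV, absolute).
#'
#' @return A tibble with column `time` (ms), one row per spike; zero rows
#'   when no spike fired.
#' @examples
#' tr <- hh_simulate(protocol = stimulus_protocol(amplitude = 3, duration = 5))
#' detect_spikes(tr) # one spike
#' @export
detect_spikes <- function(trace, threshold = 0) {
  check_trace(trace)
  V <- trace$V_m
  k <- which(V[-length(V)] < threshold & V[-1] >= threshold)
  if (length(k) == 0) return(tibble(time = double()))
  frac <- (threshold - V[k]) / (V[k + 1] - V[k])
  tibble(time = trace$t[k] + frac * (trace$t[k + 1] - trace$t[k]))
}

#' Run one complete simulation-and-energetics experiment
#'
#' Deterministic composition of the whole pipeline: simulate the membrane,
#' evaluate the power decomposition, the energy report, the current/power
#' synchrony, and the ratio and fraction summaries. The same inputs always
#' produce identical output (there is no randomness anywhere in the model).
#'
#' @param params A [membrane_params()] object.
#' @param protocol A [stimulus_protocol()] object.
#' @param include_stimulus Passed to [energy_consumption()].
#' @param spike_threshold Spike detection threshold (mV).
#'
#' @return An object of class `hh_run`: a list with elements `trace`,
#'   `power`, `energy` (one-row tibble), `synchrony` (one-row tibble),
#'   `spikes`, `ratio`, `fractions`, `stim_ratio` (`NULL` for a zero
#'   stimulus), `params`, `protocol`. Use [glance()] for a one-row summary
#'   or [tidy()] for a long metric table.
#' @examples
#' run <- run_experiment(protocol = stimulus_protocol(amplitude = 3, duration = 5))
#' glance(run)[, c("eta", "spiked")]
#' @export
run_experiment <- function(params = membrane_params(),
                           protocol = stimulus_protocol(),
                           include_stimulus = FALSE,
                           spike_threshold = 0) {
  trace <- hh_simulate(params, protocol)
  power <- power_series(trace, params)
  energy <- energy_report(trace, power, params,
                          include_stimulus = include_stimulus,
                          spike_threshold = spike_threshold)
  # degenerate membranes (e.g. a channel conductance of 0) have identically
  # zero current series; report NA synchrony rather than failing the run
  synchrony <- tryCatch(
    synchrony_report(trace, power),
    hh_undefined_synchrony = function(e) {
      tibble(tau_I = NA_real_, psi_I = NA_real_,
             tau_E = NA_real_, psi_E = NA_real_)
    }
  )
  structure(
    list(
      trace = trace,
      power = power,
      energy = energy,
      synchrony = synchrony,
      spikes = detect_spikes(trace, spike_threshold),
      ratio = power_ratio_series(power),
      fractions = power_fraction_series(power),
      stim_ratio = if (any(power$p_stim != 0)) stimulus_power_ratio(power) else NULL,
      params = params,
      protocol = protocol
    ),
    class = "hh_run"
  )
}

#' @export
print.hh_run <- function(x, ...) {
  e <- x$energy
  cat(sprintf("<hh_run> %g uA/cm2 x %g ms (window %g ms, dt %g ms)\n",
              x$protocol$amplitude, x$protocol$duration,
              x$protocol$t_total, x$protocol$dt))
  cat(sprintf("  regime: %s (%d spike%s)\n",
              if (e$spiked) "suprathreshold" else "subthreshold",
              nrow(x$spikes), if (nrow(x$spikes) == 1) "" else "s"))
  cat(sprintf("  Q_Na = %.4g C/cm2 -> E_s = %.4g J/cm2; E_c = %.4g J/cm2\n",
              e$Q_Na, e$E_s, e$E_c))
  if (e$eta_defined) {
    cat(sprintf("  efficiency eta = %.1f%%\n", e$eta))
  } else {
    cat("  efficiency undefined (zero energy supply)\n")
  }
  cat(sprintf("  tau_I = %.3f (psi %.1f deg), tau_E = %.3f (psi %.1f deg)\n",
              x$synchrony$tau_I, x$synchrony$psi_I,
              x$synchrony$tau_E, x$synchrony$psi_E))
  invisible(x)
}

#' @rdname run_experiment
#' @param x An `hh_run` object.
#' @param ... Unused.
#' @method glance hh_run
#' @export
glance.hh_run <- function(x, ...) {
  dplyr::bind_cols(
    tibble(amplitude = x$protocol$amplitude,
           duration = x$protocol$duration,
           n_spikes = nrow(x$spikes)),
    x$energy,
    x$synchrony
  )
}

#' @rdname run_experiment
#' @method tidy hh_run
#' @export
tidy.hh_run <- function(x, ...) {
  g <- glance(x)
  tidyr::pivot_longer(
    dplyr::mutate(g,
                  eta_defined = as.numeric(.data$eta_defined),
                  spiked = as.numeric(.data$spiked)),
    dplyr::everything(),
    names_to = "metric", values_to = "value"
  )
}

#' Sweep a stimulus parameter across the threshold
#'
#' Repeats [run_experiment()] while varying either the stimulus amplitude or
#' its duration over a strictly increasing grid, recording the energy
#' efficiency and regime of each run. Across the firing threshold the
#' efficiency drops discontinuously from above 100% (subthreshold overdraft,
#' decreasing toward the threshold) to a narrow band near 76% that barely
#' changes with further stimulus strength.
#'
#' @param params A [membrane_params()] object.
#' @param base Baseline [stimulus_protocol()]; the varied field is replaced
#'   per run.
#' @param varied Which field to vary: `"amplitude"` (uA/cm2) or
#'   `"duration"` (ms).
#' @param values Strictly increasing grid of at least two values.
#' @param ... Passed on to [run_experiment()].
#'
#' @return A tibble of class `hh_sweep` with columns `value`, `eta`,
#'   `spiked`, `n_spikes`, `E_s`, `E_c`, `Q_Na`, and attributes `varied` and
#'   `threshold_index` (first index of the spiking regime, `NA` if the sweep
#'   never switches).
#' @examples
#' \donttest{
#' sw <- sweep_stimulus(varied = "amplitude", values = seq(2, 4, by = 0.5),
#'                      base = stimulus_protocol(duration = 3))
#' threshold_index(sw)
#' }
#' @export
sweep_stimulus <- function(params = membrane_params(),
                           base = stimulus_protocol(duration = 3),
                           varied = c("amplitude", "duration"),
                           values, ...) {
  varied <- match.arg(varied)
  check_params(params)
  check_protocol(base)
  if (!is.numeric(values) || length(values) < 2 || any(!is.finite(values)) ||
      any(diff(values) <= 0)) {
    abort("values must be >= 2 strictly increasing finite numbers",
          class = "hh_invalid_input")
  }
  rows <- lapply(values, function(v) {
    proto_args <- unclass(base)
    proto_args[[varied]] <- v
    run <- tryCatch(
      run_experiment(params, do.call(stimulus_protocol, proto_args), ...),
      error = function(e) {
        abort(sprintf("sweep failed at %s = %g: %s", varied, v, conditionMessage(e)),
              class = "hh_integration_error", parent = e)
      }
    )
    e <- run$energy
    tibble(value = v, eta = e$eta, spiked = e$spiked,
           n_spikes = nrow(run$spikes), E_s = e$E_s, E_c = e$E_c, Q_Na = e$Q_Na)
  })
  out <- bind_rows(rows)
  idx <- which(out$spiked)
  structure(out,
            varied = varied,
            threshold_index = if (length(idx) > 0) idx[1] else NA_integer_,
            class = c("hh_sweep", class(tibble())))
}

#' First spiking index of a sweep
#'
#' @param sweep An `hh_sweep` from [sweep_stimulus()].
#' @return Integer index of the first run in the spiking regime, or `NA` if
#'   the whole sweep stayed subthreshold.
#' @export
threshold_index <- function(sweep) {
  if (!inherits(sweep, "hh_sweep")) {
    abort("`sweep` must be an hh_sweep", class = "hh_invalid_input")
  }
  attr(sweep, "threshold_index")
}
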