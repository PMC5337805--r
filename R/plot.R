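## ggplot2 views of traces, power decompositions and sweeps.

#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_hline labs
#'   scale_colour_manual facet_wrap theme_minimal
NULL

channel_colours <- c(Na = "#d62728", K = "#000000", leak = "#bcbd22",
                     stimulus = "#e377c2", total = "#2ca02c")

#' Plot a membrane-potential trace
#'
#' @param object An `hh_trace` from [hh_simulate()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hh_trace <- function(object, ...) {
  ggplot(object, aes(x = .data$t, y = .data$V_m)) +
    geom_line(colour = "#1f77b4") +
    labs(x = "time (ms)", y = "membrane potential (mV)") +
    theme_minimal()
}

#' Plot the channel currents of a trace
#'
#' By convention the stored Na+ current is inward-positive; for visual
#' comparison with the outward K+ current it is drawn with reversed sign
#' when `outward_positive = TRUE` (presentation only, the trace itself is
#' untouched).
#'
#' @param trace An `hh_trace`.
#' @param outward_positive Draw all currents on the outward-positive axis?
#' @return A ggplot.
#' @export
plot_current_series <- function(trace, outward_positive = TRUE) {
  check_trace(trace)
  sgn <- if (outward_positive) -1 else 1
  df <- tibble(
    t = rep(trace$t, 4),
    current = c(sgn * trace$i_Na, sgn * trace$i_K, sgn * trace$i_l,
                trace$i_stim),
    channel = rep(c("Na", "K", "leak", "stimulus"), each = nrow(trace))
  )
  ggplot(df, aes(x = .data$t, y = .data$current, colour = .data$channel)) +
    geom_line() +
    scale_colour_manual(values = channel_colours) +
    labs(x = "time (ms)",
         y = sprintf("current (uA/cm2, %s-positive)",
                     if (outward_positive) "outward" else "inward")) +
    theme_minimal()
}

#' Plot the power decomposition of a run
#'
#' @param object An `hh_power` from [power_series()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hh_power <- function(object, ...) {
  df <- tidyr::pivot_longer(
    as_tibble(object)[, c("t", "p_Na", "p_K", "p_l", "p_stim", "p_total")],
    -"t", names_to = "channel", values_to = "power")
  df$channel <- c(p_Na = "Na", p_K = "K", p_l = "leak",
                  p_stim = "stimulus", p_total = "total")[df$channel]
  ggplot(df, aes(x = .data$t, y = .data$power, colour = .data$channel)) +
    geom_line() +
    scale_colour_manual(values = channel_colours) +
    labs(x = "time (ms)", y = "power (nW/cm2)") +
    theme_minimal()
}

#' Plot energy efficiency across a stimulus sweep
#'
#' Shows the discontinuous drop of the efficiency at the firing threshold:
#' subthreshold runs sit above 100%, spiking runs in a narrow band near 76%.
#'
#' @param object An `hh_sweep` from [sweep_stimulus()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hh_sweep <- function(object, ...) {
  varied <- attr(object, "varied")
  unit <- if (identical(varied, "amplitude")) "uA/cm2" else "ms"
  df <- as_tibble(object)
  df$regime <- ifelse(df$spiked, "suprathreshold", "subthreshold")
  ggplot(df, aes(x = .data$value, y = .data$eta, colour = .data$regime)) +
    geom_hline(yintercept = 100, linetype = "dashed", colour = "grey50") +
    geom_point() +
    geom_line(aes(group = .data$regime)) +
    labs(x = sprintf("stimulus %s (%s)", varied, unit),
         y = "energy efficiency (%)", colour = NULL) +
    theme_minimal()
}
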