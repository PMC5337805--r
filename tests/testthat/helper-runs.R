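# Shared fixtures, computed once per test run. All are deterministic, so
# memoisation is purely a speed matter.

memo <- function(fn) {
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- fn()
    cache
  }
}

supra_run <- memo(function() {
  run_experiment(protocol = stimulus_protocol(amplitude = 3, duration = 5))
})

sub_run <- memo(function() {
  run_experiment(protocol = stimulus_protocol(amplitude = 2.5, duration = 3))
})

rest_run <- memo(function() {
  run_experiment(protocol = stimulus_protocol())
})

# Small battery of extra operating points for property-style checks;
# slightly coarser step keeps them cheap while staying well converged.
battery_runs <- memo(function() {
  protos <- list(
    stimulus_protocol(amplitude = 1, duration = 3, dt = 0.01),
    stimulus_protocol(amplitude = 2, duration = 3, dt = 0.01),
    stimulus_protocol(amplitude = 4, duration = 3, dt = 0.01),
    stimulus_protocol(amplitude = 2.5, duration = 6, dt = 0.01)
  )
  lapply(protos, function(p) run_experiment(protocol = p))
})

all_runs <- memo(function() {
  c(list(supra_run(), sub_run(), rest_run()), battery_runs())
})

# Synthetic power table with the column layout power_series() produces.
make_power <- function(t, p_Na = 0, p_K = 0, p_l = 0, p_stim = 0) {
  n <- length(t)
  expand <- function(x) if (length(x) == 1) rep(x, n) else x
  p_Na <- expand(p_Na); p_K <- expand(p_K)
  p_l <- expand(p_l); p_stim <- expand(p_stim)
  tibble::tibble(t = t, p_Na = p_Na, p_K = p_K, p_l = p_l, p_stim = p_stim,
                 p_total = p_Na + p_K + p_l + p_stim)
}

# Reference trapezoid weights for hand-computed integral oracles.
trapz_weights <- function(t) {
  n <- length(t)
  w <- numeric(n)
  w[1] <- (t[2] - t[1]) / 2
  w[n] <- (t[n] - t[n - 1]) / 2
  if (n > 2) w[2:(n - 1)] <- (t[3:n] - t[1:(n - 2)]) / 2
  w
}
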