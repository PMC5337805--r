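---
title: "Energy supply and consumption of a Hodgkin-Huxley neuron"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy supply and consumption of a Hodgkin-Huxley neuron}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hhenergetics)
```

## The question

A neuron's electrical signalling is paid for by metabolism: the Na+/K+
pump burns ATP to move ions against their gradients, storing
electrochemical potential energy that the ion channels later dissipate as
heat during activity. `hhenergetics` makes both sides of that ledger
explicit for a single Hodgkin-Huxley (HH) neuron under step-current
stimulation:

* **energy supply** `E_s` — the ATP cost of pumping back out the Na+ that
  entered during the window (ion counting);
* **energy consumption** `E_c` — the time integral of the electric power
  dissipated in the channels (power integral);
* **energy efficiency** `eta = 100 * E_c / E_s`.

The central result the package reproduces is a sharp dichotomy: during a
full action potential the neuron dissipates about **76%** of the
concurrent ATP supply, while during subthreshold activity the efficiency
rises **above 100%** — an "energy overdraft" in which the channels spend
potential energy faster than the concurrent Na+ influx obliges the pump
to replace it, leaving a metabolic debt that is repaid at rest.

## The membrane model

The membrane obeys

$$C_m \frac{dV_m}{dt} = g_l (E_l - V_m) + g_{Na} m^3 h (E_{Na} - V_m)
  + g_K n^4 (E_K - V_m) + I(t),$$

with first-order kinetics $\dot{x} = \alpha_x(V_m)(1-x) - \beta_x(V_m)x$
for the gates $x \in \{n, m, h\}$. The rate functions are the classical
squid-axon forms written in the depolarisation coordinate
$u = V_m - V_r$ (positive = depolarised):

$$\alpha_n = \frac{0.1 - 0.01u}{e^{1-0.1u}-1},\quad
  \beta_n = 0.125\,e^{-u/80},\quad
  \alpha_m = \frac{2.5-0.1u}{e^{2.5-0.1u}-1},$$
$$\beta_m = 4\,e^{-u/18},\quad
  \alpha_h = 0.07\,e^{-u/20},\quad
  \beta_h = \frac{1}{e^{3-0.1u}+1}.$$

This is the unique self-consistent convention in which depolarisation
opens $n$ and $m$ and closes $h$, which is what an action potential
requires. The removable singularities of the two rational forms (at
$u = 10$ and $u = 25$ mV) are evaluated by the series limit
$x/(e^x - 1) \to 1 - x/2$ inside $|x| < 10^{-7}$.

### Parameters and defaults

| parameter | default | units | notes |
|---|---|---|---|
| `g_Na`, `g_K`, `g_l` | 120, 36, 0.3 | mS/cm2 | classical maximal conductances |
| `E_Na`, `E_K`, `E_l` | 50, −80, −56 | mV | must satisfy `E_K < E_l < E_Na` |
| `V_r` | −67.3 | mV | resting potential; also the origin of `u` |
| `C_m` | 1 | uF/cm2 | standard specific capacitance |
| `lambda_ATP` | 50e3 | J/mol | free energy per mole ATP (physiological range 46–62 kJ/mol) |
| `na_per_atp` | 3 | — | 3 Na+ out / 2 K+ in per ATP |
| `e_charge`, `N_A` | CODATA | C, 1/mol | exact SI values |
| `dt` | 0.005 | ms | fixed RK4 step |
| `t_total` | 30 | ms | integration window |

With these reversal potentials, `V_r = -67.3` mV is very nearly a true
equilibrium of the full system: the leak, Na+ and K+ currents at rest sum
to about −0.03 uA/cm2, and an unstimulated run drifts by less than
0.04 mV over the whole window (the rest-stationarity test asserts
< 0.5 mV).

### Integration

The integrator is classical fixed-step fourth-order Runge-Kutta on the
grid `seq(0, t_total, by = dt)` (driven through `deSolve::ode(method =
"rk4")`). A fixed step makes every run exactly reproducible and lets the
convergence tests make sharp statements: halving `dt` from 0.005 ms moves
the voltage by at most ~0.001 mV at any sample and every energy integral
by well under 0.5%. The spike upstroke is the fastest feature
(~500 mV/ms); 0.005 ms resolves it with hundreds of samples.

The **30 ms window** is chosen so that both canonical transients (spike
or subthreshold bump plus their after-potentials) are fully complete and
the trace has returned to rest with several milliseconds to spare. The
window matters more than it may look: the resting membrane carries a
steady Na+ "window" influx of about 1.24 uA/cm2, so every millisecond of
window adds to the Na+ count and to the resting dissipation on both sides
of the ledger. All reported reference numbers in the package are defined
on this window.

## The energetics layer

**Supply.** Integrating the inward Na+ current
$i_{Na} = g_{Na} m^3 h (E_{Na} - V_m)$ over the window gives the influx
charge $Q_{Na}$ (1.429 uC/cm2 for the canonical spike). Dividing by the
elementary charge gives the ion count; one ATP is spent per
`na_per_atp` = 3 ions extruded; multiplying moles of ATP by `lambda_ATP`
gives $E_s$. This chain is pure arithmetic and is tested to relative
error < 1e-12 against hand evaluation.

**Consumption.** Each channel branch dissipates
$p_x = i_x (E_x - V_m) = g_x (E_x - V_m)^2 \ge 0$; the electrode
contributes $p_{stim} = V_m I$. `energy_consumption()` integrates the
**channel dissipation** $p_{Na} + p_K + p_l$ by default. The electrode
term is energy exchanged with the external circuit rather than heat
produced in the membrane's conductances, and for a step stimulus
delivered while the membrane is below 0 mV it is a small negative
correction; it is available via `include_stimulus = TRUE` and is always
present in the `p_stim`/`p_total` columns. The same convention defines
the denominator of `power_fraction_series()` (argument
`denominator = "full"` restores the electrode-inclusive total).

**Charge balance.** For any protocol that returns to rest, the integrated
net outward ionic charge equals the injected stimulus charge to within
2% — the capacitor ends where it started, so the ions crossing the
membrane can only neutralise what the electrode injected (15 nC/cm2 for
the spike run, 7.52 vs 7.5 nC/cm2 subthreshold).

**Efficiency guard.** `eta` is undefined when `E_s = 0`; `efficiency()`
raises a dedicated condition and `energy_report()` flags the row instead
of emitting a number. Note that a *resting* neuron does not trigger the
guard: the resting Na+ window flux keeps `E_s` finite, and an
unstimulated window reports `eta` near 113% — rest itself runs a small
overdraft in this accounting. The guard is for genuinely degenerate
membranes (e.g. `g_Na = 0`).

## Synchrony and power structure

`synchronicity()` is the cosine of the angle between two series under the
L2 inner product (trapezoidal quadrature on the grid), and the phase
difference is its arccosine. Applied to the signed Na+/K+ currents and
to the two channel powers of the same run it yields the signature the
efficiency dichotomy rides on:

* spiking: `tau_I = -0.987` (currents almost perfectly antiphase),
  `tau_E = 0.782`;
* subthreshold: `tau_I = -0.90`, `tau_E = 0.96`.

The sign pattern (currents negative, powers positive) and both orderings
(|tau_I| larger when spiking, tau_E larger subthreshold) are exact claims
tested without tolerance.

Ratio and fraction series need a denominator floor to avoid 0/0 after
recovery: a sample is defined only where the denominator exceeds
`1e-6` of its window maximum; masked samples are excluded from all
min/max claims. During a spike the Na+ share of channel power is bimodal
(upstroke and recovery, peaks ~0.88) with a K+-dominated trough at the
voltage peak; subthreshold the Na+ channel dominates throughout and the
joint Na+K share stays near or above 70% (computed minimum ~0.69, during
the post-stimulus recovery). The magnitude ratio of total to stimulus
power separates the regimes by orders of magnitude: ~3x10^5 at the spike
("blasting fuse": the trigger's own power is negligible) versus < 6
subthreshold.

## Sweeps and the threshold

`sweep_stimulus()` repeats the full pipeline over a grid of amplitudes
(default use case: 1.0–6.0 uA/cm2 at 3 ms) or durations (1.0–8.0 ms at
2.5 uA/cm2). Both sweeps show the same picture: subthreshold efficiency
decreases monotonically from ~112% toward the threshold, then drops
discontinuously to a band of 76.0–76.3% that barely changes with further
stimulus strength (spread < 0.3 percentage points across each sweep).

One genuine model property deserves emphasis: the two regimes are *not*
separated by the 100% line all the way to the threshold. In a narrow
boundary layer just below threshold — about 0.2 uA/cm2 wide in amplitude,
0.4 ms in duration — the response is still subthreshold (peak
depolarisation ~8 mV, nowhere near a spike) yet its efficiency crosses
100% continuously and reaches ~93% at the last subthreshold grid point.
A sweep with a step of 0.1 samples this layer; a coarser grid, such as a
figure-resolution sweep, skips it and shows two cleanly separated groups.
The package reports what the model does; the boundary layer is a property
of the energetics, not a numerical artifact (it is stable under dt
halving).

Spike detection uses a fixed upward crossing of 0 mV, which is
unambiguous for full-height spikes (overshoot ~ +37 mV) against graded
responses (< −59 mV everywhere in the tested ranges). Multi-spike runs
report efficiency over the whole window and carry their spike count so
single-spike comparisons can exclude them.

## The energy-form Hebbian rule

For two neurons with power traces $P_i(t)$, $P_j(t)$ the instantaneous
weight-change rate is the windowed correlation

$$k\,\frac{d\omega_{ji}}{dt} = \int_0^\infty \left[ P_i(\tau)H(\tau)
  P_j(t-\tau) + P_i(t-\tau)H(-\tau)P_j(\tau) \right] d\tau,$$

truncated at a configurable `support` and evaluated by trapezoidal
quadrature on the shared trace grid. The time window $H$ is
user-supplied; the default is an exponentially decaying, sign-split
kernel $H(\tau) = e^{-|\tau|/\tau_H}$ for $\tau \ge 0$ and
$-\,\text{asymmetry}\cdot e^{-|\tau|/\tau_H}$ for $\tau < 0$, with
$\tau_H = 5$ ms — a spike-timing-style asymmetry with a documented knob
(`asymmetry = -1` gives a symmetric window). `k` defaults to 1, so rates
are reported per unit rate constant. The rule is bilinear in the two
powers, exact against a double-loop evaluation on short grids, and
converges under support doubling once $H$ has decayed (< 1% change).
Which power to correlate (total or channel-restricted) is left to the
caller; any series on the common grid is accepted.

## Scope and limitations

* Single compartment, current-step stimuli only: no channel noise, no
  temperature scaling, no cable geometry, no synaptic conductances.
* The pump is an accounting device: its electrogenic current does not
  feed back on `V_m`, and ATP production kinetics are not modelled.
* The stored-energy constant of the membrane (capacitor plus Nernst
  "batteries") is unknowable in this framework; only power and its
  integrals over a window are reported.
* Reference values are defined on the default 30 ms window; shorter
  windows shrink both sides of the ledger by the resting contribution and
  move subthreshold efficiencies by several percentage points.
* The boundary layer described above means "subthreshold implies
  overdraft" holds except within ~0.2 uA/cm2 (or ~0.4 ms) of threshold.

## Problem sizes

The default grid is 6001 samples per run (30 ms at 0.005 ms). The full
test battery runs a few dozen single runs plus two 51- and 71-point
sweeps; everything is deterministic, so repeated runs are bit-identical.
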