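---
title: "Model and methods: rhythm generation by NMDAR feedback in electrically coupled populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(swimnet)
```

# The scientific question

Hatchling *Xenopus* tadpoles swim for seconds after a brief touch and stop
abruptly on head pressure. The rhythm is driven by ~30 electrically
coupled reticulospinal descending interneurons (dINs) per side which
excite each other through glutamatergic synapses. `swimnet` implements a
conductance-based model of this population to ask how mutual NMDAR
feedback, its magnesium-dependent voltage sensitivity, and gap-junction
coupling produce sustained, switchable rhythm — and whether the same
feedback mechanism works in populations of generic Hodgkin–Huxley
neurons.

# The membrane model

Neurons are chains of cylindrical compartments. With outward current
positive, each compartment obeys

$$C \frac{dV}{dt} = -\sum_k i_k - i_{syn} + i_{inj} + i_{axial} + i_{gap}$$

Hodgkin–Huxley-type currents are $i = \bar g \prod_j x_j^{e_j}(V-E)$ with
gate dynamics $\dot x = \alpha(V)(1-x) - \beta(V)x$. All rate functions
use one generalised form $(A + BV)/(C + e^{(D+V)/E})$, which covers the
classic squid shapes (used verbatim for the generic neuron) and the
Boltzmann/constant-$\tau$ gates of the dIN set; removable singularities
are replaced by their analytic limits. The calcium current uses the
Goldman–Hodgkin–Katz constant-field equation with fixed internal (0.1 µM)
and external (10 mM) calcium — the model keeps no calcium state, so no
buffering or accumulation is represented.

## The dIN parameter set is a package default, not a measurement

Voltage-clamp data for dINs are unavailable (they are electrically
coupled, which defeats single-cell clamp), so no published kinetics pin
the channel parameters. The shipped dIN set (`din_soma_channels()`,
`din_axon_channels()`) was therefore tuned, once, to the behavioural
constraints the biology fixes: resting potential near −57 mV with high
input resistance (the cells are ~10 µm); repetitive firing at 5–30 Hz
under sustained NMDAR conductances around 0.5–2 nS and a firing threshold
lower without the Mg²⁺ block than with it; depolarising block at high
non-voltage-dependent drive; and a start-protocol rhythm that dies at
0.07 nS/synapse feedback, sustains in the 15–30 Hz half-CNS band at
0.11 nS, and runs faster at 0.15 nS. The slow potassium gate (τ = 30 ms)
paces repetitive firing; the soma is 12 µm, the axon 0.3 µm × 600 µm in
20 µm compartments behind a 1 µm × 60 µm initial segment. All of this is
config: every density, rate coefficient and geometric parameter can be
overridden, and the defaults ship as YAML under `inst/extdata/`.

# Synapses

Chemical synaptic conductance is the difference of two decaying
exponentials, normalised so one event peaks at exactly `g_peak`
(`synapse_peak()` gives the peak time and normalisation). One millisecond
after the presynaptic soma crosses 0 mV (detected with hysteresis: no
re-trigger until the trace falls below −10 mV), A and B step up by 1; with
`transmission_p < 1` the event is delivered with that probability,
independently per synapse. The NMDAR current is multiplied by the
magnesium-block factor $1/(1+\eta[\mathrm{Mg}^{2+}]_o e^{-\gamma V})$
with η = 0.1 mM⁻¹, γ = 0.08 mV⁻¹ and 0.5 mM magnesium; "zero-Mg" runs set
the factor to 1. Receptor time constants: feedback NMDA 5/80 ms, feedback
AMPA 0.1/3 ms, GABA-A 1.5/20 ms (E = −70 mV), bath-perfusion NMDA 5 ms
opening with a 10 s closing. Excitatory reversal potentials default to
0 mV. Receptor desensitisation, short-term plasticity and NMDAR
saturation are out of scope.

Because the two exponentials admit exact solutions, the summation of a
regular spike train has a closed form; `summation_ratio()` locates the
per-interval maximum analytically, and the test suite checks it against a
brute-force fine-step integration of the state equations. For the 80 ms
closing time the summed conductance stays below three times the unitary
peak across the 10–25 Hz swimming band — the property that lets feedback
accumulate without running away.

# Networks

`build_din_population()` places somata at 0, −10, −20, … µm (rostral =
larger coordinate; descending axons run caudally). For every ordered
rostral→caudal pair whose axon overlaps the caudal soma, one 600 MΩ gap
junction connects the rostral neuron's axon compartment nearest the
caudal soma to one of the caudal neuron's initial-segment compartments;
the caudal endpoint rotates across the initial segment so junctions are
distributed along it rather than stacked on one tiny compartment (which
would also be a physically implausible point load). Feedback connections
are sampled independently at p = 0.2 per ordered pair, each carrying an
AMPA and an NMDA component onto the soma, with truncated-normal
peak-conductance multipliers of relative variance 0.1.
`build_generic_population()` instead couples 30 single-compartment squid-
parameter neurons soma-to-soma (100 MΩ, p = 0.2 per unordered pair) with
the same feedback sampling and, additionally, channel-density noise
(relative sd 0.1 — the magnitude is a package choice).

# Stimulus models

The tIN sensory model draws, per tIN, a spike count from a
stimulus-dependent distribution anchored at the experimental constraints
P(1 spike | s = 95%) = 0.5, P(1 | 100%) = 1, P(1 | s > 120%) = 0.3. Between
anchors the distribution interpolates linearly and monotonically in s;
above 100% the residual mass falls geometrically (ratio 0.5) on counts
2–5. Spike times are per-slot normals with defaults μₖ = 10 + 8(k−1) ms,
σₖ = 2 + 1.5(k−1) ms. The anchors are data; the interpolation, the
geometric tail and the timing defaults are package choices, marked as
such and overridable. Each of 20 tINs contacts every dIN; each spike
causes an EPSP in each dIN with probability 0.5, independently per
(spike, dIN) pair — the per-pair reading of unreliable transmission. The
tIN→dIN synaptic weight (0.4 nS per receptor component) was set so a
threshold-strength volley recruits the whole population.

The MHR stop input is a burst of n spikes at a fixed interval delivered
synchronously to every dIN through the GABA-A synapse; the duration of
inhibition is (n−1)·ISI. NMDA perfusion is modelled as an identical
conductance drive in every neuron: a dual-exponential waveform (5 ms
opening, 10 s closing) normalised so its plateau equals the target
conductance.

# Numerics

Fixed-step integration, default dt = 0.025 ms. Gates advance by exact
exponential update using rates tabulated on a 0.05 mV grid; gate states
are staggered at half steps, so the update is second-order centred.
Voltages use the trapezoidal (θ = 0.5) scheme, with the ohmic and
synaptic conductances evaluated at the step midpoint and axial coupling
solved per neuron by the Thomas algorithm. Gap junctions couple different
neurons and sit outside that solve: a stable semi-implicit predictor is
followed by trapezoidal corrector iterations against the partner's
midpoint voltage, which restores second-order accuracy while remaining
stable where several junctions converge on one small compartment.
Nonlinear factors (Mg block, GHK) are evaluated at an extrapolated
midpoint voltage. Synaptic deliveries snap to the nearest step boundary.
Numerical blow-up (|V| > 200 mV) aborts with a diagnostic rather than
returning garbage. The convergence contract is tested: halving dt moves
network spike times by well under 0.5 ms over a one-second start-protocol
run.

Randomness is split into component streams (connectivity and conductance
noise; tIN spike draws; sensory transmission; synaptic transmission inside
the engine) derived from one master seed, so any component can be
replayed in isolation; runs are bit-reproducible given (network, stimuli,
config).

# Analysis definitions

* Firing frequency: spike count in a window divided by its length; the
  sustained-phase window starts 300 ms after the sensory volley.
* Sustained: at least one spike in the final 300 ms of the run;
  "reliably sustained" means sustained in ≥ 90% of seeds. Both rules are
  operationalisations chosen here — the source experiments report the
  behaviour qualitatively.
* Synchrony index: variance of the 5 ms-binned pooled spike count divided
  by its value under same-rate independent homogeneous-Poisson
  surrogates, mapped to [0, 1] via (R−1)/(n−1). Perfectly coincident
  trains score near 1 (about 0.9 for regular trains, since binning a
  periodic train is not Poisson), independent trains near 0. The metric
  choice is ours; the calibration cases pin it.
* Stop probability: fraction of seeded trials with no spike later than
  200 ms after the inhibition ends.

# Experiment drivers and problem sizes

The five drivers reproduce the canonical protocols: `run_perfusion()`
(steady-state depolarisation with sodium removed, and firing frequency,
each with and without Mg²⁺), `run_summation()`, `run_start()` /
`run_start_sweep()` (volley at 100 ms; classification against the
15–30 Hz half-CNS band), `run_stop()` / `run_stop_grid()` (burst at
700 ms; n = 1–5 spikes × 10/15/20 ms ISI), and `run_generic()` /
`run_generic_sweep()` (volley at 100 ms for 150 ms — the excitation
duration is not constrained by the source description, so it is exposed
as config — and optional inhibitory bursts of 10 events at 7 ms
intervals). Default run lengths are 1.1–1.5 s of simulated time with the
full 30-neuron populations; the test suite uses the same populations, a
reduced stop grid (two seeds per cell) and 1.2–1.5 s runs, which keeps
the whole suite in the tens of minutes while exercising every
figure-level claim. Each driver writes CSV tables, JSON spike rasters and
a manifest from the CLI.

# What the synthetic protocols do and do not show

All inputs are generated: the tIN volley, the MHR burst and the perfusion
ramp emulate the experimental stimuli, under the stated parametric
assumptions, with no biological variability beyond the modelled noise
terms. Passing tests therefore demonstrate internal consistency of the
mechanism — mutual NMDAR feedback with voltage dependence widening the
stable range, electrical coupling synchronising without being required
for persistence, inhibition duration governing stop reliability — not
quantitative agreement with any particular animal. Known limitations:
the dIN channel kinetics are behavioural reconstructions, not fits to
voltage-clamp data; firing can exceed observed tadpole maxima at strong
drive; zero-Mg rhythm occurs in the model though not in experiments; the
bilateral network with commissural inhibition is out of scope.
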