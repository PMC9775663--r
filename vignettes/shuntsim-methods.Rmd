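---
title: "Behavioral models in shuntsim: from subthreshold inverters to spike-pattern detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavioral models in shuntsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shuntsim)
```

## What the package models

`shuntsim` is a behavioral simulator of an analog silicon synapse whose
output stage emulates a resistor between the postsynaptic membrane and a
configurable synaptic reversal potential `E_syn`. That resistor-like
element is what distinguishes a *conductance-based* synapse,

$$I_{syn}(t) = g_{syn}(t)\,(V_{mem}(t) - E_{syn}),$$

from the *current-based* synapses common in low-power neuromorphic chips,
which emit a stereotyped current independent of the postsynaptic
potential. The dependence on `V_mem` is what makes **shunting
inhibition** possible: a synapse whose reversal potential sits near the
resting potential barely moves the membrane on its own but raises the
local conductance, attenuating concurrent excitatory postsynaptic
potentials.

The package covers four layers, each usable on its own:

1. **Oscillator core** — closed-form switching times of subthreshold CMOS
   inverters, the ring-oscillator frequency they imply, and an
   independent ODE oracle for validating the closed forms.
2. **Synapse** — a four-bit DAC charges a gate variable linearly during a
   ~2 ms input pulse; a constant current discharges it linearly; an
   exponential converter maps the gate to the synaptic conductance. The
   output is either a smooth current or the oscillatory charge-packet
   train produced by the ring-oscillator-gated transconductance stage.
3. **Neuron** — a leaky integrate-and-fire (LIF) stand-in soma, wired
   either as a single-compartment point neuron behind a current conveyor
   that clamps the shared postsynaptic node, or as a unidirectional
   two-compartment neuron with a dendritic RC node coupled one-way into
   the soma.
4. **Plasticity and task** — adaptive rectangular STDP on the four-bit
   efficacies, the inhomogeneous-Poisson stimulus generator with an
   embedded repeating spike pattern, and the detection experiment with
   hit/false-alarm scoring.

## Subthreshold inverter timing

In weak inversion the pull-down device discharges the inverter output
following

$$C_{out}\frac{dV_{out}}{dt} = -I_{0}\,
  e^{(\kappa V_g - V_{in})/U_T}\left(1 - e^{-(V_{out}-V_{in})/U_T}\right),$$

which integrates in closed form to the high-to-low switching time
implemented by `discharge_time()` (and its pull-up mirror
`charge_time()`). `ode_transition_oracle()` integrates the same equation
numerically (adaptive `lsodar`, relative tolerance `1e-8`, body effect
ignored) and agrees with the closed forms to well under 1 %; the test
suite checks a 100-point random grid.

`propagation_time()` is the large-swing simplification. One numerical
note: the exact mean of the fall/rise times carries a factor
$x/2 + \log(1+e^{-x/2})$ with $x$ the swing in thermal-voltage units;
the simplified form keeps only $x/2$, so the thermal voltage cancels out
of the prefactor and $t_P \propto C_{out}(V_{dd}-V_{in})$. Within its
stated regime (rail headroom above $4U_T$) the simplification stays
within 15 % of the exact mean. The ring frequency uses the standard
relation $f = 1/(2 n_{stages} t_P)$ for an `n_stages`-stage ring; no
other formula is implied by the circuit description, so we adopt the
textbook one. With the default device constants the frequency covers the
2–25 kHz operating band as the lower rail moves through its working
range, and `log f` is affine in the rail voltage.

For asymmetric devices `propagation_time()` uses the geometric mean of
the current scale factors and the arithmetic mean of the coupling
ratios; the closed forms themselves take each device's own constants.

## The synapse calibration

All synapse parameters are *behavioral*: they stand in for bias voltages
of the circuit and are expressed in simulation units (V for the gate
variable, nS for conductance, mV for potentials, pA for currents —
chosen so that nS × mV = pA).

The default (characterization) calibration of `synapse_config()` was
fixed once against the circuit-level observations the model must
reproduce for a *single synaptic event*:

* gate charge rate 25 V/s per efficacy step, discharge 20 V/s, pulse
  2 ms — the gate peaks at pulse end (the alpha-like rise) and
  discharges linearly;
* conductance $g = g_{unit} e^{V_{gate}/U_{T,eff}}$ with
  $U_{T,eff} = 90$ mV, so the synaptic current decays exponentially
  with $\tau = U_{T,eff}/\text{discharge rate} = 4.5$ ms, inside the
  3–5 ms range of fast AMPA-like kinetics;
* the oscillator-frequency map reaches ≈2.4 kHz at efficacy 1 and
  ≈17.7 kHz at efficacy 15;
* the asymmetric driving-force function `phi_iv()` uses
  $V_\alpha = 25$ mV, $V_\beta = 250$ mV, making the emulated
  resistance exponentially larger for $E_{syn} < V_{mem}$ (the measured
  I–V asymmetry), while keeping $\Phi(0)=0$ and unit slope at the
  origin.

Two modeling choices deserve emphasis.

**The gate ceiling.** The physical gate node is bounded by the supply
rail. The behavioral `gate_max` reproduces this: closely spaced inputs
saturate instead of stacking without bound. Without the ceiling an
exponential converter driven by sustained ~50 Hz input would produce
heavy-tailed, super-additive conductance bursts (and, at high
efficacies, unbounded growth), which the real circuit cannot.

**Ideal-linear DAC with an exponential converter.** The DAC is modeled
as exactly binary-weighted (charge rate ∝ efficacy). Because the
converter is exponential and the decay time constant is fixed, the
peak-current-versus-efficacy curve is necessarily convex; the measured
hardware curve is *sublinear* (≈6.8× from efficacy 1 to 15), which the
behavioral model does not attempt to reproduce. Peak conductance is
monotone in efficacy, which is what the learning dynamics require. This
gap is a known limitation, rooted in unmodeled device-level
nonlinearities of the fabricated DAC.

**Oscillatory output.** In oscillatory mode the synaptic current is
delivered as rectangular charge packets occupying a fixed duty fraction
(default 0.5) of each oscillator period, with the packet charge equal to
the smooth current integrated over the period. Packet emission uses an
exact phase integral, so charge is conserved by construction; a 5 ms
moving average of the packet train matches the smooth model within 10 %
whenever the oscillator runs at 2 kHz or faster. The pulse shape at the
output of the switched-capacitor stage is not documented for the
circuit; the rectangular-packet choice is constrained only through the
moving-average behavior.

## Neuron configurations

The silicon soma itself is a qualitative spiking circuit whose internal
equations are out of scope here; the package substitutes a leaky
integrate-and-fire soma with an absolute refractory period, which
preserves the two properties the experiments rely on: Class 1
excitability (a continuous f–I curve) and the absence of
spike-frequency adaptation. Spike times are recovered by linear
interpolation inside the integration step, and the default fixed step is
0.1 ms (a convergence check at 0.01 ms is part of the test suite).

In the **single-compartment** configuration the current conveyor clamps
the shared postsynaptic node, so every conductance-mode synapse sees a
constant `V_post_clamp` and the summed current is replicated into the
soma (`conveyor_sum()`, with a polarity-reversing branch available). The
package uses a single depolarizing-positive sign convention for all
synaptic modes; the chip's internally inverted polarity (a PMOS-soma
implementation artifact) is deliberately not modeled, so the
"reversed" conveyor branch is plain arithmetic rather than a physical
necessity.

In the **unidirectional two-compartment** configuration the synapses
charge a dendritic RC node (8.5 pF, with the leak implemented — as in
the circuit — by one synapse held in conductance mode at a fixed gate),
and the dendrite drives the soma through an Ohmic coupling resistance
with *no back-action*: the dendritic trajectory is bit-identical under
any soma manipulation, which the tests check literally.

### Shunting-inhibition demonstration

`shunting_protocol()` reproduces the on-chip demonstration with the
default `shunting_calibration()`: one current-based excitatory synapse
produces a clear dendritic EPSP; the shunting synapse alone (reversal
10 mV above the dendritic rest, matching the relative spacing used on
chip) produces no deflection; co-activation attenuates the EPSP by
≈34 % (the chip measured 34.6 % ± 1.65 %); and with synchronous
maximal-efficacy excitation exactly four synapses make the soma spike,
four plus the shunt do not, and five plus the shunt do. The coupling
resistance and leak conductance have no documented values; they are
calibration constants fixed once by those spike counts.

## Adaptive rectangular STDP

Each synapse stores a four-bit efficacy `w ∈ [0, 15]` updated by ±1:

* **LTP**: a postsynaptic spike at $t_i$ increments every synapse whose
  most recent presynaptic spike $t_j$ satisfies $t_j \le t_i$ and
  $t_i - t_j < t_{pre}$ (simultaneous spikes potentiate, never
  depress);
* **LTD**: a presynaptic spike at $t_j$ decrements its synapse when the
  most recent postsynaptic spike satisfies $t_j > t_i$ and
  $t_j - t_i < t_{post}$.

Nearest-spike memory (one remembered pre spike per synapse, one shared
post spike) matches the single-timing-capacitor learning circuit better
than all-pairs bookkeeping. The adaptive element is the non-decreasing
schedule of $t_{post}$; the hardware drives it from an external bias
with no documented voltage-to-milliseconds mapping, so the schedule
shape and values here are the package's own calibration (below). An
event-driven implementation is used everywhere; the test suite checks
it against a brute-force replay oracle on random event streams.

## The stimulus generator

The generator emulates the detection task's input: 256 independent
afferents, instantaneous rates performing a slew-limited random walk in
[0, 90] Hz (uniform increments at 1 ms resolution, reflected at the
bounds, so a full 0→90 Hz sweep takes at least 50 ms), thinning-based
inhomogeneous Poisson sampling, at least one spike per afferent per
50 ms window (empty windows receive one uniformly placed spike), and a
randomly chosen 50 ms section copied into a quarter (or a tenth) of the
sections with no two consecutive replacements — the non-adjacent
subset is drawn uniformly via the standard gap bijection, and the
copied section's own position counts as an occurrence.

Under this construction the long-run mean rate is ≈45 Hz before the
activity floor and ≈49.5 Hz after it (the floor contributes about
$20\,\mathrm{E}[e^{-r/20}] \approx 4.5$ Hz), measured identically
inside and outside pattern occurrences — the pattern is hidden in the
rate and distinguishable only by spike timing. Note the inside/outside
*equality* is the construction goal; the absolute level depends on the
stationary distribution of the rate walk, and a walk construction with
more dwell time at the bounds would sit a few Hz higher.

What the generator does *not* emulate: correlated afferents, jittered
or partial patterns, multiple patterns, and any non-stationarity beyond
the rate walk. Detection results on this stimulus therefore speak to
the synapse and learning model under the task's own idealized input,
not to arbitrary natural spike statistics.

## The detection experiment and its calibration

`run_detection()` wires one synapse per afferent (any output mode) to
the clamped single-compartment neuron and runs the full train at
dt = 0.1 ms with event-exact spike bookkeeping (the inner loop is
compiled; the conductance of each synapse evolves by per-step
multiplicative factors, which is exact for the piecewise-linear gate).
Scoring follows the task definition: in the final 75 s, a hit is an
occurrence containing at least one soma spike, a false alarm is a soma
spike outside every occurrence, and success means a hit rate above 98 %
with zero false alarms. Occurrences truncated by the window edge are
excluded from both accountings, and the hit window is the occurrence
interval itself (a configurable extension exists and defaults to zero).

The task calibration (`detection_synapse_config()`,
`detection_network_config()`, `detection_learning_params()`) differs
from the characterization calibration in the DAC drive strength —
mirroring the circuit practice of setting the weight-bias differently
per experiment — and was fixed, once, by the following reasoning:

* Under sustained ~50 Hz input the per-pulse gate charge must stay
  below the inter-event discharge so the conductance remains a
  transient, alpha-like kernel (charge rate 6 V/s per step).
* The efficacy-to-conductance curve must be flat enough that the
  initial state (256 synapses at efficacy 8) and the learned state
  (a several-dozen-synapse ensemble at efficacy 15) straddle a *fixed*
  soma threshold: the initial state must fire while the learned
  background must stay strictly silent. The per-step conductance ratio
  is ≈1.14. Even so, the two requirements compete: with the threshold
  placed high enough for a silent learned background, the uniform
  initial state fires at only ~5–15 Hz rather than the 40–200 Hz the
  hardware reported — a compromise made in favor of end-state
  selectivity and noted as a deviation in the result checks.
* The soma integrates as a coincidence detector (τ_m = 1.5 ms), and its
  refractory period (20 ms) caps the early, potentiation-dominated
  firing so that depression — whose rate is bounded by the afferent
  rate — can take over as the window widens.
* The depression-window schedule has three phases: a short bootstrap,
  a long consolidation hold just above the potentiation/depression
  balance point $(1 - e^{-r t_{pre}})/r$ (at which the net drift of an
  uncorrelated synapse nearly vanishes and the only systematic force is
  the pattern-locked potentiation of afferents that reliably precede
  the soma's in-pattern spikes), and a final step to a much wider
  window that rapidly depresses everything not protected by that
  locked potentiation. After the step, successful runs settle at one
  soma spike per occurrence and silence elsewhere, with the efficacy
  histogram collapsed onto the two saturation values.

The learning trajectory is a genuinely stochastic race between
ensemble consolidation and background pruning; runs whose ensembles
lock late or weakly can fail, which is why the batch success rate — not
any single run — is the reported quantity, matching how the hardware
experiments were summarized (50 runs per condition).

Problem sizes used by the packaged checks: the acceptance script runs
the full-size experiment (256 afferents, 225 s, 50 runs per repetition
frequency); the unit tests exercise scaled versions (64 afferents,
5–20 s) with the conductance scale raised in proportion, which
preserves the operating point of every mechanism while keeping the
suite fast.

## Numerical choices and degenerate inputs

* Fixed-step integration at 0.1 ms; forward Euler for the membrane
  (τ_m ≥ 1.5 ms) and exact per-step updates for gates and
  conductances. The dt/10 convergence checks compare spike counts and
  early spike times; trajectory-level agreement over long horizons is
  not expected for a threshold system.
* The oscillator phase accumulates as a real number; packet on-fractions
  use an exact integral, so no aliasing error accumulates even when the
  period is shorter than the step.
* Ordering inside one step: input events are processed before the soma
  update; at exactly equal timestamps presynaptic events precede
  postsynaptic ones, so simultaneous pairs take the potentiation branch.
* Degenerate scoring windows (no complete occurrence) are flagged
  `degenerate` and never divide by zero; `success` is `FALSE` for them.
* A repeat fraction above 0.5 (infeasible without adjacent copies) and
  malformed event files are rejected with specific errors.

## Known limitations

* The efficacy-to-peak-current curve is convex rather than the measured
  sublinear hardware curve (see above).
* The LIF stand-in reproduces Class 1 excitability and refractoriness
  but none of the richer subthreshold dynamics of the qualitative soma
  circuit, nor its measured thermal noise; detection success rates are
  therefore calibration-dependent and are compared to the hardware
  results at the batch level only.
* Static leakage currents (fA-scale), power consumption, back-gate
  control, and charge-injection effects are out of scope.
* The depression-window schedule is an open-loop calibration; the chip
  likewise drove it from an external source, but its actual profile is
  not documented.
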