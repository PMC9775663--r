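#' Synapse circuit configuration
#'
#' Behavioral parameters of one synapse circuit: a four-bit binary-weighted
#' DAC charges the gate variable linearly for the duration of an input pulse,
#' a constant current discharges it linearly, and an exponential converter
#' turns the linear gate into the synaptic conductance. Three output modes
#' are available: stereotyped excitatory or inhibitory current (independent
#' of the postsynaptic potential) and a conductance mode implementing
#' `I = g * (E_syn - V_mem)`-type behavior through the asymmetric
#' piecewise-exponential I-V [phi_iv()].
#'
#' Defaults are a single calibration chosen so that (i) the synaptic current
#' decays with a time constant `U_T_eff / discharge_rate` = 4.5 ms, in the
#' 3-5 ms range typical of AMPA-like kinetics; (ii) the oscillator frequency
#' map reaches ~2.4 kHz at efficacy 1 and ~17.7 kHz at efficacy 15 (see
#' [freq_calibration()]); and (iii) the asymmetry `V_beta >> V_alpha` makes
#' the emulated resistance exponentially larger for `E_syn < V_mem`.
#'
#' @param mode One of `"conductance"`, `"excitatory_current"`,
#'   `"inhibitory_current"`.
#' @param E_syn Synaptic reversal potential, mV (conductance mode only).
#' @param charge_rate Gate charge rate per unit efficacy during an input
#'   pulse, V/s per efficacy step.
#' @param discharge_rate Constant gate discharge rate, V/s.
#' @param gate_floor Gate value below which the linear-discharge regime ends
#'   and the oscillator is off, V.
#' @param pulse_width Input pulse duration, s.
#' @param gate_max Gate ceiling, V (the supply rail bounds the gate node;
#'   overlapping inputs saturate rather than stack without bound).
#' @param g_unit Conductance scale, nS.
#' @param U_T_eff Exponential gate-to-conductance scale, V.
#' @param V_alpha Exponential I-V scale for `E_syn > V_mem`, mV.
#' @param V_beta Exponential I-V scale for `E_syn < V_mem`, mV; must exceed
#'   `V_alpha` (asymmetry).
#' @param s_exc,s_inh Current-mode drive scales, mV (so `g * s` is in pA).
#' @param duty Duty fraction of the oscillatory charge packets.
#' @param freq A [freq_calibration()] mapping the gate to the oscillator
#'   frequency (oscillatory mode).
#'
#' @return An object of class `synapse_config`.
#' @export
synapse_config <- function(mode = c("conductance", "excitatory_current",
                                    "inhibitory_current"),
                           E_syn = 50, charge_rate = 25, discharge_rate = 20,
                           gate_floor = 0.005, pulse_width = 2e-3,
                           gate_max = 1.0, g_unit = 2e-6, U_T_eff = 0.09,
                           V_alpha = 25, V_beta = 250,
                           s_exc = 3000, s_inh = 3000,
                           duty = 0.5, freq = freq_calibration()) {
  mode <- match.arg(mode)
  stopifnot(
    charge_rate > 0, discharge_rate > 0, gate_floor >= 0, pulse_width > 0,
    gate_max > gate_floor, g_unit > 0, U_T_eff > 0, V_alpha > 0,
    V_beta > V_alpha,
    s_exc > 0, s_inh > 0, duty > 0, duty <= 1,
    inherits(freq, "freq_calibration")
  )
  structure(
    list(mode = mode, E_syn = E_syn, charge_rate = charge_rate,
         discharge_rate = discharge_rate, gate_floor = gate_floor,
         pulse_width = pulse_width, gate_max = gate_max,
         g_unit = g_unit, U_T_eff = U_T_eff,
         V_alpha = V_alpha, V_beta = V_beta, s_exc = s_exc, s_inh = s_inh,
         duty = duty, freq = freq),
    class = "synapse_config"
  )
}

#' Synapse state
#'
#' @param V_gate Gate variable, V (>= 0).
#' @param w Four-bit synaptic efficacy, integer in 0..15.
#' @param pulse_start,pulse_until Active input-pulse interval, s
#'   (`-Inf` when no pulse has been applied).
#' @param phase Oscillator phase in cycles (oscillatory mode bookkeeping).
#' @return An object of class `synapse_state`.
#' @export
synapse_state <- function(V_gate = 0, w = 8L, pulse_start = -Inf,
                          pulse_until = -Inf, phase = 0) {
  stopifnot(V_gate >= 0, w >= 0, w <= 15)
  structure(
    list(V_gate = V_gate, w = as.integer(w), pulse_start = pulse_start,
         pulse_until = pulse_until, phase = phase),
    class = "synapse_state"
  )
}

#' Apply an input pulse to a synapse
#'
#' Marks the DAC pulse active on `[t, t + pulse_width]`. While the pulse is
#' active the gate charges at `charge_rate * w`; overlapping pulses extend
#' the active interval rather than stacking (a single input device drives
#' the DAC).
#'
#' @param state A [synapse_state()].
#' @param t Pulse onset time, s (>= 0).
#' @param cfg A [synapse_config()].
#' @return The updated state.
#' @export
apply_input_pulse <- function(state, t, cfg) {
  stopifnot(inherits(state, "synapse_state"), t >= 0,
            inherits(cfg, "synapse_config"))
  if (t > state$pulse_until) state$pulse_start <- t
  state$pulse_until <- max(state$pulse_until, t + cfg$pulse_width)
  state
}

#' Advance the synapse gate by one time step
#'
#' Integrates the gate over `[t, t + dt)`: linear charging at
#' `charge_rate * w` while the input pulse is active, minus the constant
#' `discharge_rate`, clamped at zero. The returned state carries a
#' `below_floor` attribute flagging when the gate is under `gate_floor`
#' (the discharge device leaves saturation; oscillator off).
#'
#' @inheritParams apply_input_pulse
#' @param dt Step duration, s (> 0).
#' @return The updated state.
#' @export
step_gate <- function(state, t, dt, cfg) {
  stopifnot(inherits(state, "synapse_state"), dt > 0,
            inherits(cfg, "synapse_config"))
  overlap <- max(0, min(t + dt, state$pulse_until) - max(t, state$pulse_start))
  dv <- cfg$charge_rate * state$w * overlap - cfg$discharge_rate * dt
  state$V_gate <- min(max(0, state$V_gate + dv), cfg$gate_max)
  attr(state, "below_floor") <- state$V_gate < cfg$gate_floor
  state
}

#' Simulate the gate trace for a train of input pulses
#'
#' Fixed-step simulation of the gate variable of a single synapse driven by
#' presynaptic spike times, returning a tidy trace.
#'
#' @param spike_times Presynaptic spike times, s.
#' @param cfg A [synapse_config()].
#' @param w Synaptic efficacy (0..15).
#' @param t_end End of the simulated window, s.
#' @param dt Step, s.
#' @return A tibble with columns `time` and `V_gate`.
#' @export
gate_trace <- function(spike_times, cfg, w = 15L, t_end = 0.05, dt = 1e-4) {
  st <- synapse_state(w = w)
  times <- seq(0, t_end, by = dt)
  ev <- sort(spike_times)
  out <- numeric(length(times))
  k <- 1L
  for (i in seq_along(times)) {
    t <- times[i]
    while (k <= length(ev) && ev[k] < t + dt) {
      st <- apply_input_pulse(st, ev[k], cfg)
      k <- k + 1L
    }
    out[i] <- st$V_gate
    st <- step_gate(st, t, dt, cfg)
  }
  tibble::tibble(time = times, V_gate = out)
}

#' Synaptic conductance from the gate variable
#'
#' Exponential conversion of the linear gate:
#' `g = g_unit * exp(V_gate / U_T_eff)` for `V_gate > 0`, and 0 at rest.
#' Because the gate discharges linearly, the conductance decays
#' exponentially with time constant `U_T_eff / discharge_rate`.
#'
#' @inheritParams apply_input_pulse
#' @return Conductance in nS.
#' @export
conductance <- function(state, cfg) {
  stopifnot(inherits(state, "synapse_state"),
            inherits(cfg, "synapse_config"))
  if (state$V_gate <= 0) return(0)
  cfg$g_unit * exp(state$V_gate / cfg$U_T_eff)
}

#' Asymmetric synaptic I-V shape
#'
#' Continuous piecewise-exponential driving-force function used by the
#' conductance mode: `phi(x) = V_alpha * (exp(x / V_alpha) - 1)` for
#' `x >= 0` and `-V_beta * (1 - exp(x / V_beta))` for `x < 0`, with
#' `phi(0) = 0` and unit slope at the origin. With `V_beta >> V_alpha` the
#' current is exponentially larger for `E_syn > V_mem` than for the mirrored
#' difference, reproducing the asymmetric I-V of the transconductance stage.
#'
#' @param x Driving force `E_syn - V_mem`, mV.
#' @param V_alpha,V_beta Exponential scales, mV.
#' @return Effective driving force, mV.
#' @export
phi_iv <- function(x, V_alpha = 25, V_beta = 250) {
  ifelse(x >= 0,
         V_alpha * expm1(x / V_alpha),
         -V_beta * (1 - exp(x / V_beta)))
}

#' Synaptic current
#'
#' Instantaneous synaptic current in the depolarizing-positive convention:
#' excitatory current mode gives `+g * s_exc` (independent of `V_mem`),
#' inhibitory current mode `-g * s_inh`, and conductance mode
#' `g * phi_iv(E_syn - V_mem)` which reverses sign at `V_mem = E_syn`.
#'
#' @inheritParams apply_input_pulse
#' @param V_mem Postsynaptic membrane potential, mV.
#' @return Current in pA (positive depolarizes the postsynaptic node).
#' @export
synaptic_current <- function(state, cfg, V_mem) {
  g <- conductance(state, cfg)
  switch(cfg$mode,
    excitatory_current = g * cfg$s_exc,
    inhibitory_current = -g * cfg$s_inh,
    conductance = g * phi_iv(cfg$E_syn - V_mem, cfg$V_alpha, cfg$V_beta)
  )
}

# Fraction of the phase interval [phase, phase + dphase) lying in the "on"
# half of each oscillator cycle (frac(phi) < duty). Exact, so the packet
# train conserves charge against the smooth model by construction.
packet_on_fraction <- function(phase, dphase, duty) {
  if (dphase <= 0) return(0)
  Fint <- function(x) floor(x) * duty + pmin(x - floor(x), duty)
  (Fint(phase + dphase) - Fint(phase)) / dphase
}

#' Oscillatory (charge-packet) synaptic current
#'
#' The transconductance stage delivers the synaptic current as charge
#' packets gated by the ring oscillator: within each oscillator period the
#' smooth current's charge is emitted as a rectangular pulse occupying the
#' `duty` fraction of the period. This returns the mean current over
#' `[t, t + dt)` of that packet train (exact integral of the rectangular
#' waveform), together with the state carrying the advanced phase. The
#' time-average over windows much longer than one period equals the smooth
#' model; with the oscillator off (`f_inst = 0`) no current flows.
#'
#' @inheritParams synaptic_current
#' @param f_inst Instantaneous oscillator frequency, Hz (>= 0).
#' @param t Step start time, s.
#' @param dt Step duration, s (> 0).
#' @return A list with elements `current` (pA, mean over the step) and
#'   `state` (updated phase).
#' @export
oscillatory_current <- function(state, cfg, V_mem, f_inst, t, dt) {
  stopifnot(dt > 0, f_inst >= 0)
  if (f_inst == 0) {
    return(list(current = 0, state = state))
  }
  i_smooth <- synaptic_current(state, cfg, V_mem)
  on_frac <- packet_on_fraction(state$phase, f_inst * dt, cfg$duty)
  state$phase <- state$phase + f_inst * dt
  list(current = i_smooth * on_frac / cfg$duty, state = state)
}
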