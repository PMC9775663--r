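#' Stand-in soma parameters
#'
#' Leaky integrate-and-fire stand-in for the silicon soma, configured as a
#' Class 1 (continuous f-I curve), non-adapting spiker: linear leaky
#' integration, threshold crossing with linearly interpolated spike time,
#' reset, and an absolute refractory period.
#'
#' @param C_mem Membrane capacitance, pF.
#' @param g_leak Leak conductance, nS.
#' @param V_rest Resting potential, mV.
#' @param V_thresh Spiking threshold, mV (`!= V_rest`).
#' @param V_reset Post-spike reset potential, mV.
#' @param t_refr Absolute refractory period, s.
#' @return An object of class `soma_params`.
#' @export
soma_params <- function(C_mem = 10, g_leak = 1, V_rest = -70,
                        V_thresh = -45, V_reset = -70, t_refr = 3e-3) {
  stopifnot(C_mem > 0, g_leak > 0, t_refr > 0, V_thresh != V_rest)
  structure(
    list(C_mem = C_mem, g_leak = g_leak, V_rest = V_rest,
         V_thresh = V_thresh, V_reset = V_reset, t_refr = t_refr),
    class = "soma_params"
  )
}

#' Soma state constructor
#'
#' @param params A [soma_params()].
#' @return A list with fields `V` (mV) and `refr_until` (s).
#' @export
soma_state <- function(params) {
  list(V = params$V_rest, refr_until = -Inf)
}

#' Advance the soma by one step
#'
#' Forward-Euler leaky integrate-and-fire update over `[t, t + dt)`. On a
#' threshold crossing the continuous-time spike time is recovered by linear
#' interpolation within the step, the potential resets, and the membrane
#' holds at reset for the refractory period.
#'
#' @param state A [soma_state()].
#' @param I_in Total input current over the step, pA (depolarizing
#'   positive).
#' @param t Step start time, s.
#' @param dt Step, s; must not exceed 0.5 ms.
#' @param params A [soma_params()].
#' @return A list `(state, spike, t_spike)`; `t_spike` is NA without a
#'   spike.
#' @export
step_soma <- function(state, I_in, t, dt, params) {
  stopifnot(dt > 0, dt <= 5e-4)
  t_spike <- NA_real_
  spike <- FALSE
  if (t < state$refr_until) {
    state$V <- params$V_reset
  } else {
    v_old <- state$V
    dv <- 1000 * dt *
      (params$g_leak * (params$V_rest - v_old) + I_in) / params$C_mem
    v_new <- v_old + dv
    if (v_new >= params$V_thresh && dv > 0) {
      frac <- (params$V_thresh - v_old) / dv
      t_spike <- t + frac * dt
      spike <- TRUE
      state$V <- params$V_reset
      state$refr_until <- t_spike + params$t_refr
    } else {
      state$V <- v_new
    }
  }
  list(state = state, spike = spike, t_spike = t_spike)
}

#' Simulate the soma under a prescribed current
#'
#' @param I Current, pA: a constant, or a vector with one value per step.
#' @param t_end Simulated duration, s.
#' @param dt Step, s.
#' @param params A [soma_params()].
#' @return A list with `trace` (tibble `time`, `V`) and `spikes`
#'   (interpolated spike times, s).
#' @export
simulate_soma <- function(I, t_end, dt = 1e-4, params = soma_params()) {
  n <- round(t_end / dt)
  I <- rep_len(I, n)
  st <- soma_state(params)
  v <- numeric(n)
  spikes <- numeric(0)
  for (i in seq_len(n)) {
    t <- (i - 1) * dt
    v[i] <- st$V
    res <- step_soma(st, I[i], t, dt, params)
    st <- res$state
    if (res$spike) spikes <- c(spikes, res$t_spike)
  }
  list(trace = tibble::tibble(time = (seq_len(n) - 1) * dt, V = v),
       spikes = spikes)
}

#' Dendritic compartment parameters
#'
#' RC dendritic node of the unidirectional two-compartment configuration:
#' a dendritic capacitor integrates the synaptic currents, a leak is
#' provided by one synapse circuit in the conductance-based configuration
#' held at a fixed gate, and the node drives the soma one-way through the
#' coupling resistance with no back-action.
#'
#' @param C_den Dendritic capacitance, pF (default 8.5).
#' @param R_c Unidirectional coupling resistance, megaohm.
#' @param leak_synapse A [synapse_config()] in conductance mode acting as
#'   the leak resistor, with reversal `E_syn = E_leak`.
#' @param leak_gate Fixed gate value of the leak synapse, V.
#' @return An object of class `dendrite_params`.
#' @export
dendrite_params <- function(C_den = 8.5, R_c = 100,
                            leak_synapse = synapse_config(
                              mode = "conductance", E_syn = -60,
                              g_unit = 1e-4),
                            leak_gate = 0.8) {
  stopifnot(C_den > 0, R_c > 0,
            inherits(leak_synapse, "synapse_config"),
            leak_synapse$mode == "conductance", leak_gate >= 0)
  structure(
    list(C_den = C_den, R_c = R_c, leak_synapse = leak_synapse,
         leak_gate = leak_gate),
    class = "dendrite_params"
  )
}

#' Advance the dendritic node by one step
#'
#' `C_den dV/dt = sum(I_syn) + I_leak(V_den)`; the soma and the coupling
#' resistor have no effect on the dendrite (unidirectionality).
#'
#' @param V_den Dendritic potential, mV.
#' @param synapse_currents Synaptic currents, pA (depolarizing positive).
#' @param params A [dendrite_params()].
#' @param dt Step, s.
#' @return The updated dendritic potential, mV.
#' @export
step_dendrite <- function(V_den, synapse_currents, params, dt) {
  stopifnot(inherits(params, "dendrite_params"), dt > 0)
  leak_state <- synapse_state(V_gate = params$leak_gate, w = 15L)
  i_leak <- synaptic_current(leak_state, params$leak_synapse, V_den)
  V_den + 1000 * dt * (sum(synapse_currents) + i_leak) / params$C_den
}

#' Unidirectional coupling current
#'
#' Ohmic current delivered to the soma only:
#' `I = (V_den - V_mem) / R_c`, in pA for mV and megaohm. Both signs are
#' permitted at the soma; the dendrite is unaffected.
#'
#' @param V_den,V_mem Dendritic and somatic potentials, mV.
#' @param R_c Coupling resistance, megaohm (> 0).
#' @return Current into the soma, pA.
#' @export
coupling_current <- function(V_den, V_mem, R_c) {
  stopifnot(R_c > 0)
  1000 * (V_den - V_mem) / R_c
}

#' Current-conveyor summation
#'
#' The conveyor clamps the shared postsynaptic node and replicates the
#' summed synaptic current into the soma through one of two branches with
#' opposite polarities.
#'
#' @param synapse_currents Currents, pA.
#' @param polarity `"same"` or `"reversed"`.
#' @return The summed (possibly negated) current, pA.
#' @export
conveyor_sum <- function(synapse_currents, polarity = c("same", "reversed")) {
  polarity <- match.arg(polarity)
  s <- sum(synapse_currents)
  if (polarity == "reversed") -s else s
}

#' Network wiring configuration
#'
#' @param configuration `"single_compartment"` (conveyor-clamped
#'   postsynaptic node; all conductance-mode synapses see
#'   `V_mem = V_post_clamp`) or `"two_compartment_unidirectional"`.
#' @param V_post_clamp Clamped postsynaptic node voltage, mV.
#' @param soma A [soma_params()].
#' @param dendrite A [dendrite_params()] (two-compartment mode).
#' @param polarity Conveyor branch used in single-compartment mode.
#' @return An object of class `network_config`.
#' @export
network_config <- function(configuration = c("single_compartment",
                                             "two_compartment_unidirectional"),
                           V_post_clamp = -70,
                           soma = soma_params(),
                           dendrite = dendrite_params(),
                           polarity = "same") {
  configuration <- match.arg(configuration)
  structure(
    list(configuration = configuration, V_post_clamp = V_post_clamp,
         soma = soma, dendrite = dendrite, polarity = polarity),
    class = "network_config"
  )
}

#' Calibration of the shunting-inhibition demonstration
#'
#' Default parameter set for [run_shunting_demo()], chosen so that under
#' synchronous maximal-efficacy activation exactly four excitatory synapse
#' circuits make the soma spike, four plus the single shunting synapse do
#' not, and five plus the shunting synapse do.
#'
#' @param exc A [synapse_config()] for the current-based excitatory
#'   synapses.
#' @param shunt A [synapse_config()] for the shunting synapse; its reversal
#'   sits a few mV above the dendritic resting potential.
#' @param dendrite A [dendrite_params()].
#' @param soma A [soma_params()].
#' @param t_on Input pulse onset, s.
#' @param t_end Simulated duration, s.
#' @param dt Step, s.
#' @return A list of class `shunting_calibration`.
#' @export
shunting_calibration <- function(
    exc = synapse_config(mode = "excitatory_current", g_unit = 2.5e-6),
    shunt = synapse_config(mode = "conductance", E_syn = -60,
                           g_unit = 9e-4),
    dendrite = dendrite_params(),
    soma = soma_params(C_mem = 10, g_leak = 1, V_rest = -70,
                       V_thresh = -44, V_reset = -70, t_refr = 3e-3),
    t_on = 0.02, t_end = 0.12, dt = 1e-4) {
  structure(list(exc = exc, shunt = shunt, dendrite = dendrite,
                 soma = soma, t_on = t_on, t_end = t_end, dt = dt),
            class = "shunting_calibration")
}

#' Run one trial of the shunting-inhibition protocol
#'
#' Simulates the unidirectional two-compartment neuron with `n_exc`
#' synchronous current-based excitatory synapses and optionally one
#' conductance-based shunting synapse, all at maximal efficacy, activated
#' by a single input pulse.
#'
#' @param n_exc Number of synchronously activated excitatory synapses.
#' @param shunt Activate the shunting synapse as well?
#' @param cal A [shunting_calibration()].
#' @return A list with `trace` (tibble `time`, `V_den`, `V_soma`),
#'   `epsp_peak` (mV above dendritic rest), and `soma_spikes`.
#' @export
run_shunting_demo <- function(n_exc = 1, shunt = FALSE,
                              cal = shunting_calibration()) {
  stopifnot(inherits(cal, "shunting_calibration"), n_exc >= 0)
  dt <- cal$dt
  n <- round(cal$t_end / dt)
  den <- cal$dendrite
  v_rest_den <- den$leak_synapse$E_syn

  exc_st <- synapse_state(w = 15L)
  shunt_st <- synapse_state(w = 15L)
  exc_st <- apply_input_pulse(exc_st, cal$t_on, cal$exc)
  shunt_st <- apply_input_pulse(shunt_st, cal$t_on, cal$shunt)

  v_den <- v_rest_den
  soma_st <- soma_state(cal$soma)
  spikes <- numeric(0)
  tr_den <- numeric(n)
  tr_soma <- numeric(n)

  for (i in seq_len(n)) {
    t <- (i - 1) * dt
    tr_den[i] <- v_den
    tr_soma[i] <- soma_st$V

    i_exc <- if (n_exc > 0) {
      n_exc * synaptic_current(exc_st, cal$exc, v_den)
    } else 0
    i_shunt <- if (shunt) {
      synaptic_current(shunt_st, cal$shunt, v_den)
    } else 0
    v_den <- step_dendrite(v_den, c(i_exc, i_shunt), den, dt)

    i_soma <- coupling_current(tr_den[i], soma_st$V, den$R_c)
    res <- step_soma(soma_st, i_soma, t, dt, cal$soma)
    soma_st <- res$state
    if (res$spike) spikes <- c(spikes, res$t_spike)

    exc_st <- step_gate(exc_st, t, dt, cal$exc)
    shunt_st <- step_gate(shunt_st, t, dt, cal$shunt)
  }
  list(
    trace = tibble::tibble(time = (seq_len(n) - 1) * dt,
                           V_den = tr_den, V_soma = tr_soma),
    epsp_peak = max(tr_den) - v_rest_den,
    soma_spikes = spikes
  )
}

#' Full shunting-inhibition protocol
#'
#' Reproduces the on-chip demonstration: (1) one excitatory synapse alone
#' gives a clear dendritic EPSP; (2) the shunting synapse alone barely
#' deflects the dendrite; (3) both together attenuate the EPSP; and the
#' spike-count runs in which four synchronous excitatory synapses make the
#' soma spike, four plus the shunting synapse do not, and five plus the
#' shunting synapse do.
#'
#' @param cal A [shunting_calibration()].
#' @return A tibble with one row per run: `run`, `n_exc`, `shunt`,
#'   `epsp_peak` (mV), `n_spikes`, and `epsp_attenuation` (fractional
#'   reduction of run 3 vs run 1, on the co-activation row).
#' @export
shunting_protocol <- function(cal = shunting_calibration()) {
  r1 <- run_shunting_demo(1, FALSE, cal)
  r2 <- run_shunting_demo(0, TRUE, cal)
  r3 <- run_shunting_demo(1, TRUE, cal)
  r4 <- run_shunting_demo(4, FALSE, cal)
  r5 <- run_shunting_demo(4, TRUE, cal)
  r6 <- run_shunting_demo(5, TRUE, cal)
  runs <- list(r1, r2, r3, r4, r5, r6)
  tibble::tibble(
    run = c("exc_alone", "shunt_alone", "exc_plus_shunt",
            "four_exc", "four_exc_plus_shunt", "five_exc_plus_shunt"),
    n_exc = c(1, 0, 1, 4, 4, 5),
    shunt = c(FALSE, TRUE, TRUE, FALSE, TRUE, TRUE),
    epsp_peak = vapply(runs, function(r) r$epsp_peak, numeric(1)),
    n_spikes = vapply(runs, function(r) length(r$soma_spikes), integer(1)),
    epsp_attenuation = c(NA, NA, 1 - r3$epsp_peak / r1$epsp_peak,
                         NA, NA, NA)
  )
}
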