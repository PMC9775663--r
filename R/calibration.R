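#' Detection-task synapse calibration
#'
#' Synapse configuration used by the spike-pattern detection experiment.
#' It differs from the single-event characterization defaults of
#' [synapse_config()] in the DAC drive strength (the behavioral stand-in
#' for the chip's `sVw` bias, which the chip likewise sets differently for
#' the characterization and the detection experiment): under sustained
#' 50 Hz-scale afferent input, the per-pulse gate charge must stay small
#' relative to the inter-event discharge so the gate returns to rest
#' between events and the conductance keeps its transient, alpha-like
#' shape. With the default `charge_rate` of 5 V/s per efficacy step,
#' efficacies of 5 and above produce events (the pulse must out-charge the
#' constant discharge) and the peak conductance spans about a factor 3
#' from efficacy 5 to 15. The oscillator map is recalibrated to the same
#' 2-25 kHz operating band over this smaller gate excursion.
#'
#' @param g_unit Conductance scale, nS.
#' @param charge_rate DAC charge rate per efficacy step, V/s.
#' @param ... Further overrides passed to [synapse_config()].
#' @return A [synapse_config()] object.
#' @export
detection_synapse_config <- function(g_unit = 1.6e-4, charge_rate = 6,
                                     freq = freq_calibration(
                                       f_unit = 15000, V_f = 0.3,
                                       gate_floor = 0.004), ...) {
  synapse_config(
    mode = "conductance", E_syn = 50,
    charge_rate = charge_rate, discharge_rate = 20,
    gate_floor = 0.004, pulse_width = 2e-3, gate_max = 0.15,
    g_unit = g_unit, U_T_eff = 0.09,
    freq = freq,
    ...
  )
}

#' Detection-task network configuration
#'
#' Single-compartment wiring for the detection experiment: the conveyor
#' clamps the shared postsynaptic node 120 mV below the synaptic reversal
#' potential, and the soma stand-in is calibrated so that its saturated
#' firing rate (set by the refractory period) sits below the rate at which
#' potentiation would outpace the afferent-rate-limited depression, letting
#' the adaptive depression window prune pattern-uncorrelated synapses.
#'
#' @param t_refr Soma refractory period, s.
#' @param V_thresh Soma threshold, mV.
#' @param ... Further overrides passed to [soma_params()].
#' @return A [network_config()] object.
#' @export
detection_network_config <- function(t_refr = 0.020, V_thresh = -14,
                                     C_mem = 1.5, ...) {
  network_config(
    configuration = "single_compartment",
    V_post_clamp = -70,
    soma = soma_params(C_mem = C_mem, g_leak = 1, V_rest = -70,
                       V_thresh = V_thresh, V_reset = -70,
                       t_refr = t_refr, ...)
  )
}

#' Detection-task learning schedule
#'
#' Adaptive-STDP parameters used by the spike-pattern detection experiment.
#' The depression window follows a piecewise-linear profile with three
#' phases: (1) a short bootstrap in which depression is weak and the
#' initial potentiation-dominated phase establishes activity; (2) a long
#' consolidation hold just above the potentiation/depression balance point
#' (`(1 - exp(-r * t_pre)) / r` at the mean afferent rate `r`), during
#' which the soma's spikes phase-lock to the embedded pattern and the
#' pattern-aligned ensemble saturates; and (3) a final step to a much wider
#' window that rapidly depresses every synapse not protected by reliable
#' pattern-locked potentiation, silencing the background.
#'
#' @param t_pre Potentiation window, s.
#' @param hold Consolidation depression window, s.
#' @param drain Pre-step depression window (slightly above balance), s.
#' @param final Final depression window, s.
#' @param t_consolidate,t_drain,t_step Phase boundaries, s.
#' @return A [learning_params()] object with a piecewise schedule.
#' @export
detection_learning_params <- function(t_pre = 0.006, hold = 0.0056,
                                      drain = 0.0060, final = 0.0135,
                                      t_consolidate = 50, t_drain = 100,
                                      t_step = 135) {
  learning_params(
    t_pre = t_pre, schedule = "piecewise",
    knot_times = c(0, t_consolidate, t_drain, t_step, t_step + 3),
    knot_values = c(0.003, hold, drain, drain, final)
  )
}
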