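test_that("gate charging is linear in efficacy with the DAC's binary weighting", {
  cfg <- synapse_config()
  inc <- function(w) {
    st <- synapse_state(w = w)
    st <- apply_input_pulse(st, 0, cfg)
    st <- step_gate(st, 0, cfg$pulse_width, cfg)
    st$V_gate
  }
  # zero efficacy leaves the gate untouched (clamped at zero)
  expect_equal(inc(0), 0)
  # net rise: charge_rate*w - discharge_rate over the pulse
  base <- cfg$discharge_rate * cfg$pulse_width
  expect_equal(inc(8) + base, 2 * (inc(4) + base), tolerance = 1e-12)
})

test_that("gate peaks at pulse end and then discharges linearly to zero", {
  cfg <- synapse_config()
  tr <- gate_trace(0.005, cfg, w = 8, t_end = 0.06, dt = 1e-5)
  t_peak <- tr$time[which.max(tr$V_gate)]
  expect_equal(t_peak, 0.005 + cfg$pulse_width, tolerance = 2e-5)
  peak <- max(tr$V_gate)
  expect_equal(peak, (cfg$charge_rate * 8 - cfg$discharge_rate) *
                 cfg$pulse_width, tolerance = 1e-3)

  # linear discharge arithmetic
  st <- synapse_state(V_gate = 0.2)
  cfg40 <- synapse_config(discharge_rate = 40)
  st <- step_gate(st, 0, 1e-3, cfg40)
  expect_equal(st$V_gate, 0.16)

  # time to the oscillator floor has the exact linear-decay closed form
  t_floor <- (peak - cfg$gate_floor) / cfg$discharge_rate
  after <- tr[tr$time > t_peak, ]
  crossing <- min(after$time[after$V_gate <= cfg$gate_floor]) - t_peak
  expect_equal(crossing, t_floor, tolerance = 1e-3)

  # gate never exceeds the rail ceiling however many pulses arrive
  many <- gate_trace(seq(0, 0.2, by = 0.002), cfg, w = 15, t_end = 0.25)
  expect_true(all(many$V_gate <= cfg$gate_max + 1e-12))
})

test_that("conductance is zero at rest and decays with tau = U_T_eff/discharge", {
  cfg <- synapse_config()
  expect_equal(conductance(synapse_state(V_gate = 0), cfg), 0)

  tr <- gate_trace(0.001, cfg, w = 15, t_end = 0.04, dt = 1e-5)
  dec <- tr[tr$time > 0.004 & tr$V_gate > 0.02, ]
  g <- vapply(dec$V_gate, function(v) {
    conductance(synapse_state(V_gate = v), cfg)
  }, numeric(1))
  fit <- stats::lm(log(g) ~ dec$time)
  tau_fit <- -1 / stats::coef(fit)[[2]]
  tau_expect <- cfg$U_T_eff / cfg$discharge_rate
  expect_lt(abs(tau_fit - tau_expect) / tau_expect, 0.05)
  # default calibration keeps the decay in the 3-5 ms AMPA-like band
  expect_gte(tau_expect, 3e-3)
  expect_lte(tau_expect, 5e-3)
})

test_that("peak conductance is monotone non-decreasing in efficacy", {
  cfg <- synapse_config()
  peaks <- vapply(1:15, function(w) {
    tr <- gate_trace(0.001, cfg, w = w, t_end = 0.02, dt = 1e-5)
    max(vapply(tr$V_gate, function(v) {
      conductance(synapse_state(V_gate = v), cfg)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(peaks) >= 0))
})

test_that("conductance-mode current reverses at E_syn with asymmetric magnitude", {
  st <- synapse_state(V_gate = 0.3)
  cfg <- synapse_config(mode = "conductance", E_syn = 0)
  expect_equal(synaptic_current(st, cfg, 0), 0)
  # sign flips across the reversal potential
  expect_gt(synaptic_current(st, cfg, -10), 0)
  expect_lt(synaptic_current(st, cfg, +10), 0)
  # driving from below is exponentially stronger than from above
  ratio <- abs(synaptic_current(st, cfg, -100)) /
    abs(synaptic_current(st, cfg, +100))
  expect_gt(ratio, 5)
  # phi is continuous with unit slope at the origin
  expect_equal(phi_iv(0), 0)
  expect_equal(phi_iv(1e-6) / 1e-6, 1, tolerance = 1e-4)
  expect_equal(phi_iv(-1e-6) / -1e-6, 1, tolerance = 1e-4)
})

test_that("current modes ignore the postsynaptic potential", {
  st <- synapse_state(V_gate = 0.3)
  exc <- synapse_config(mode = "excitatory_current")
  inh <- synapse_config(mode = "inhibitory_current")
  i1 <- synaptic_current(st, exc, -70)
  i2 <- synaptic_current(st, exc, +40)
  expect_equal(i1, i2)
  expect_gt(i1, 0)
  expect_lt(synaptic_current(st, inh, -70), 0)
})

test_that("oscillatory packets conserve charge and track the smooth current", {
  cfg <- synapse_config()
  run_event <- function() {
    st <- synapse_state(w = 15L)
    st <- apply_input_pulse(st, 0, cfg)
    dt <- 1e-5
    n <- 4000
    i_packet <- numeric(n)
    i_smooth <- numeric(n)
    for (k in seq_len(n)) {
      t <- (k - 1) * dt
      f <- frequency_transient_from_gate(
        tibble::tibble(time = t, V_gate = st$V_gate), cfg$freq)$frequency
      out <- oscillatory_current(st, cfg, -70, f, t, dt)
      st <- out$state
      i_packet[k] <- out$current
      i_smooth[k] <- synaptic_current(st, cfg, -70)
      st <- step_gate(st, t, dt, cfg)
    }
    list(packet = i_packet, smooth = i_smooth, dt = dt)
  }
  ev <- run_event()
  # total delivered charge matches the smooth model within 2 percent
  q_p <- sum(ev$packet) * ev$dt
  q_s <- sum(ev$smooth) * ev$dt
  expect_lt(abs(q_p - q_s) / q_s, 0.02)

  # 5 ms moving average matches the smooth current within 10 percent
  w <- round(0.005 / ev$dt)
  ker <- rep(1 / w, w)
  ma_p <- stats::filter(ev$packet, ker, sides = 2)
  ma_s <- stats::filter(ev$smooth, ker, sides = 2)
  live <- !is.na(ma_p) & ma_s > 0.25 * max(ma_s, na.rm = TRUE)
  expect_lt(max(abs(ma_p[live] - ma_s[live]) / ma_s[live]), 0.10)

  # oscillator off -> no current at all
  st <- synapse_state(V_gate = 0.3)
  expect_equal(oscillatory_current(st, cfg, -70, 0, 0, 1e-4)$current, 0)
})
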