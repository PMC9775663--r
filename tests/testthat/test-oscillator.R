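test_that("discharge time scales as the subthreshold exponential demands", {
  p <- ref_inverter()
  d1 <- oscillator_drive(Vdd_osc = 0.7, Vin_osc = 0.05, Vg = 0.6,
                         V_initial = 0.6)
  d2 <- oscillator_drive(Vdd_osc = 0.7, Vin_osc = 0.05,
                         Vg = 0.6 + p$U_T / p$kappa_n, V_initial = 0.6)
  # raising the gate by U_T/kappa speeds the pull-down by exactly e
  expect_equal(discharge_time(p, d1) / discharge_time(p, d2), exp(1),
               tolerance = 1e-12)

  # output capacitance enters as a pure linear prefactor
  p10 <- inverter_params(I0_n = p$I0_n, I0_p = p$I0_p, kappa_n = p$kappa_n,
                         kappa_p = p$kappa_p, C_out = 10 * p$C_out,
                         U_T = p$U_T)
  expect_equal(discharge_time(p10, d1), 10 * discharge_time(p, d1),
               tolerance = 1e-12)
})

test_that("charge time mirrors discharge under device and drive symmetry", {
  p <- ref_inverter()
  Vdd <- 0.6; Vin <- 0.1
  mid <- (Vdd + Vin) / 2
  vg_fall <- Vdd - 0.05
  d_fall <- oscillator_drive(Vdd, Vin, Vg = vg_fall,
                             V_initial = Vdd - 0.02)
  # the matching pull-up drive: equal gate overdrive in the exponent
  # (kappa_p * (Vdd - Vg_rise) = kappa_n * Vg_fall - Vin) and the initial
  # voltage reflected about the rail midpoint (equal swing)
  vg_rise <- Vdd - (p$kappa_n * vg_fall - Vin) / p$kappa_p
  d_rise <- oscillator_drive(Vdd, Vin, Vg = vg_rise,
                             V_initial = 2 * mid - (Vdd - 0.02))
  expect_equal(charge_time(p, d_rise), discharge_time(p, d_fall),
               tolerance = 1e-12)

  # pull-up current scaling inverts linearly
  p10 <- inverter_params(I0_n = p$I0_n, I0_p = 10 * p$I0_p,
                         kappa_n = p$kappa_n, kappa_p = p$kappa_p,
                         C_out = p$C_out, U_T = p$U_T)
  expect_equal(charge_time(p10, d_rise), charge_time(p, d_rise) / 10,
               tolerance = 1e-12)
})

test_that("closed forms agree with the ODE oracle across a random grid", {
  p <- ref_inverter()
  tab <- validate_oscillator(p, n = 50, seed = 42)
  expect_equal(nrow(tab), 100)
  expect_true(all(tab$rel_error < 0.01))
})

test_that("ODE oracle reports non-convergence when the device is off", {
  p <- ref_inverter()
  d <- oscillator_drive(Vdd_osc = 0.6, Vin_osc = 0.05, Vg = 0.05,
                        V_initial = 0.6)
  expect_error(ode_transition_oracle(p, d, "fall"), "converge")
})

test_that("ODE oracle is converged with respect to its tolerance", {
  p <- ref_inverter()
  d <- oscillator_drive(Vdd_osc = 0.6, Vin_osc = 0.05, Vg = 0.6,
                        V_initial = 0.6)
  t1 <- ode_transition_oracle(p, d, "fall", rtol = 1e-8)
  t2 <- ode_transition_oracle(p, d, "fall", rtol = 5e-9)
  expect_lt(abs(t1 - t2) / t1, 1e-4)
})

test_that("propagation time matches the mean of the full fall/rise times", {
  p <- ref_inverter()
  Vin <- 0.01
  for (headroom in seq(5, 25, by = 5) * p$U_T) {
    Vdd <- Vin + headroom
    d_fall <- oscillator_drive(Vdd, Vin, Vg = Vdd, V_initial = Vdd)
    d_rise <- oscillator_drive(Vdd, Vin, Vg = Vin, V_initial = Vin)
    m <- (discharge_time(p, d_fall) + charge_time(p, d_rise)) / 2
    tp <- propagation_time(p, d_fall)
    expect_lt(abs(tp - m) / m, 0.15)
  }
  # regime guard
  d_bad <- oscillator_drive(Vin + 3 * p$U_T, Vin)
  expect_error(propagation_time(p, d_bad), "regime")
})

test_that("propagation time rises with the lower rail; U_T scaling is linear", {
  p <- ref_inverter()
  tps <- vapply(seq(0.05, 0.2, by = 0.05), function(vin) {
    propagation_time(p, oscillator_drive(0.6, vin))
  }, numeric(1))
  expect_true(all(diff(tps) > 0))

  # doubling U_T with voltages rescaled to hold the exponent fixed:
  # the prefactor is linear in the rail swing (the thermal voltage cancels
  # against the half-swing log term in the large-swing limit)
  p2 <- inverter_params(I0_n = p$I0_n, I0_p = p$I0_p, kappa_n = p$kappa_n,
                        kappa_p = p$kappa_p, C_out = p$C_out,
                        U_T = 2 * p$U_T)
  d1 <- oscillator_drive(0.6, 0.1)
  d2 <- oscillator_drive(1.2, 0.2)
  expect_equal(propagation_time(p2, d2),
               2 * propagation_time(p, d1), tolerance = 1e-10)
})

test_that("ring frequency is log-affine in the lower rail and hits the band", {
  p <- inverter_params()  # default calibration
  vins <- seq(0.09, 0.15, by = 0.01)
  fs <- vapply(vins, function(v) {
    ring_frequency(p, oscillator_drive(0.6, v))
  }, numeric(1))
  fit <- stats::lm(log(fs) ~ vins)
  expect_gt(summary(fit)$r.squared, 0.999)
  expect_lt(stats::coef(fit)[2], 0)
  # stated operating band is reachable with the default devices
  expect_lt(min(fs), 2.6e3)
  expect_gt(max(fs), 2.0e4)

  # defining arithmetic: t_P = 33.3 us in a 3-stage ring gives ~5 kHz
  d <- oscillator_drive(0.6, 0.12, n_stages = 3)
  tp <- propagation_time(p, d)
  expect_equal(ring_frequency(p, d), 1 / (6 * tp))
  expect_equal(1 / (2 * 3 * 33.3e-6), 5005, tolerance = 1e-3)
})

test_that("frequency transient follows the gate exponentially then cuts off", {
  cal <- freq_calibration()
  # inactive oscillator
  flat <- tibble::tibble(time = seq(0, 0.01, 1e-4), V_gate = 0)
  expect_true(all(frequency_transient_from_gate(flat, cal)$frequency == 0))

  # linearly discharging gate: log-frequency is affine until the floor
  cfg <- synapse_config()
  tr <- gate_trace(0.001, cfg, w = 15, t_end = 0.04, dt = 1e-5)
  ft <- frequency_transient_from_gate(tr, cal)
  live <- ft$frequency > 0 & tr$time > 0.004
  fit <- stats::lm(log(ft$frequency[live]) ~ tr$time[live])
  expect_gt(summary(fit)$r.squared, 0.999)
  # decay rate equals discharge_rate / V_f
  expect_equal(-stats::coef(fit)[[2]], cfg$discharge_rate / cal$V_f,
               tolerance = 0.01)
  # oscillator off below the floor
  expect_true(all(ft$frequency[tr$V_gate <= cal$gate_floor] == 0))
})

test_that("default calibration reaches the stated peak frequencies", {
  cfg <- synapse_config()
  f_peak <- function(w) {
    tr <- gate_trace(0.001, cfg, w = w, t_end = 0.01, dt = 1e-5)
    max(frequency_transient_from_gate(tr, cfg$freq)$frequency)
  }
  expect_equal(f_peak(1), 2400, tolerance = 0.02)
  expect_equal(f_peak(15), 17700, tolerance = 0.02)
})
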