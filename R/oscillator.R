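#' Subthreshold inverter parameters
#'
#' Device constants of one CMOS inverter operating in the subthreshold
#' (weak-inversion) regime, where the drain current depends exponentially on
#' the gate voltage. These parameters govern the closed-form switching-time
#' expressions and the numerical transition oracle.
#'
#' @param I0_n Current scaling factor of the pull-down (NMOS) device, in A.
#' @param I0_p Current scaling factor of the pull-up (PMOS) device, in A.
#' @param kappa_n Capacitive coupling ratio (subthreshold slope factor) of the
#'   pull-down device, dimensionless, in (0, 1].
#' @param kappa_p Capacitive coupling ratio of the pull-up device, in (0, 1].
#' @param C_out Output node capacitance, in F.
#' @param U_T Thermal voltage, in V. Default 0.0258 V (300 K).
#'
#' @return An object of class `inverter_params`.
#' @examples
#' p <- inverter_params(I0_n = 1e-12, I0_p = 1e-12, kappa_n = 0.7,
#'                      kappa_p = 0.7, C_out = 5e-15)
#' @export
inverter_params <- function(I0_n = 5e-14, I0_p = 5e-14,
                            kappa_n = 0.5, kappa_p = 0.5,
                            C_out = 5e-15, U_T = 0.0258) {
  stopifnot(
    is.numeric(I0_n), I0_n > 0, is.numeric(I0_p), I0_p > 0,
    is.numeric(kappa_n), kappa_n > 0, kappa_n <= 1,
    is.numeric(kappa_p), kappa_p > 0, kappa_p <= 1,
    is.numeric(C_out), C_out > 0, is.numeric(U_T), U_T > 0
  )
  structure(
    list(I0_n = I0_n, I0_p = I0_p, kappa_n = kappa_n, kappa_p = kappa_p,
         C_out = C_out, U_T = U_T),
    class = "inverter_params"
  )
}

#' Ring-oscillator drive condition
#'
#' Supply and input voltages seen by one inverter stage of the ring
#' oscillator, plus the number of stages in the ring. `Vin_osc` is the lower
#' rail of the inverters; in the synapse circuit it is not a fixed supply but
#' is pulled down by the gate variable, which is what modulates the
#' oscillation frequency.
#'
#' @param Vdd_osc Oscillator supply voltage (upper rail), in V.
#' @param Vin_osc Oscillator lower rail voltage, in V.
#' @param Vg Inverter input gate voltage, in V.
#' @param V_initial Output-node voltage at the start of the transition, in V.
#' @param n_stages Number of inverter stages in the ring; odd, >= 3.
#'
#' @return An object of class `oscillator_drive`.
#' @export
oscillator_drive <- function(Vdd_osc = 0.6, Vin_osc = 0.12,
                             Vg = Vdd_osc, V_initial = Vdd_osc,
                             n_stages = 3L) {
  stopifnot(
    is.numeric(Vdd_osc), is.numeric(Vin_osc), Vdd_osc > Vin_osc,
    is.numeric(Vg), is.numeric(V_initial),
    n_stages >= 3, n_stages %% 2 == 1
  )
  structure(
    list(Vdd_osc = Vdd_osc, Vin_osc = Vin_osc, Vg = Vg,
         V_initial = V_initial, n_stages = as.integer(n_stages)),
    class = "oscillator_drive"
  )
}

# ln term shared by the fall/rise closed forms; x = swing / U_T > 0.
# Equals x/2 + log1p(exp(-x/2)), numerically stable for large x.
.transition_log_term <- function(x) {
  if (!is.finite(x) || x <= 0) return(NaN)
  x / 2 + log1p(exp(-x / 2))
}

#' Inverter discharge (high-to-low) time
#'
#' Closed-form time for the inverter's pull-down device to discharge the
#' output node from `V_initial` to the halfway point
#' `(V_initial + Vin_osc)/2`, assuming subthreshold operation with the body
#' effect ignored:
#' \deqn{t_{PHL} = \frac{C_{out} U_T}{I_{0,n}\,
#'   e^{(\kappa_n V_g - V_{in}) / U_T}}
#'   \ln\!\frac{1 - e^{-(V_i - V_{in})/U_T}}
#'        {e^{-(V_i - V_{in})/2U_T} - e^{-(V_i - V_{in})/U_T}}.}
#'
#' @param params An [inverter_params()] object.
#' @param drive An [oscillator_drive()] object; `Vg` should be near the upper
#'   rail for the discharge regime (the caller's responsibility).
#' @return Discharge time in seconds.
#' @seealso [charge_time()], [ode_transition_oracle()]
#' @export
discharge_time <- function(params, drive) {
  stopifnot(inherits(params, "inverter_params"),
            inherits(drive, "oscillator_drive"))
  if (drive$Vg <= drive$Vin_osc) {
    stop("discharge_time: precondition Vg > Vin_osc violated (device off)")
  }
  x <- (drive$V_initial - drive$Vin_osc) / params$U_T
  if (x <= 0) {
    stop("discharge_time: precondition V_initial > Vin_osc violated")
  }
  pref <- params$C_out * params$U_T / params$I0_n *
    exp(-(params$kappa_n * drive$Vg - drive$Vin_osc) / params$U_T)
  t <- pref * .transition_log_term(x)
  if (!is.finite(t) || t <= 0) {
    stop("discharge_time: non-finite result; drive outside the Eq. regime")
  }
  t
}

#' Inverter charge (low-to-high) time
#'
#' Mirror of [discharge_time()] for the pull-up device charging the output
#' node from `V_initial` to the halfway point `(V_initial + Vdd_osc)/2`; `Vg`
#' should be near the lower rail.
#'
#' @inheritParams discharge_time
#' @return Charge time in seconds.
#' @export
charge_time <- function(params, drive) {
  stopifnot(inherits(params, "inverter_params"),
            inherits(drive, "oscillator_drive"))
  if (drive$Vg >= drive$Vdd_osc) {
    stop("charge_time: precondition Vg < Vdd_osc violated (device off)")
  }
  x <- (drive$Vdd_osc - drive$V_initial) / params$U_T
  if (x <= 0) {
    stop("charge_time: precondition V_initial < Vdd_osc violated")
  }
  pref <- params$C_out * params$U_T / params$I0_p *
    exp(-params$kappa_p * (drive$Vdd_osc - drive$Vg) / params$U_T)
  t <- pref * .transition_log_term(x)
  if (!is.finite(t) || t <= 0) {
    stop("charge_time: non-finite result; drive outside the Eq. regime")
  }
  t
}

#' Inverter propagation time (symmetric-device closed form)
#'
#' Large-swing simplification of the mean of [discharge_time()] (evaluated at
#' `Vg = V_initial = Vdd_osc`) and [charge_time()] (at
#' `Vg = V_initial = Vin_osc`), valid for rail headroom
#' `Vdd_osc - Vin_osc > 4 U_T`:
#' \deqn{t_P = \frac{C_{out} (V_{dd} - V_{in})}
#'   {2 I_0\, e^{(\kappa V_{dd} - V_{in})/U_T}}.}
#' Symmetric devices are assumed; when `I0_n != I0_p` their geometric mean is
#' used, and the arithmetic mean of the coupling ratios.
#'
#' @inheritParams discharge_time
#' @return Propagation time in seconds.
#' @export
propagation_time <- function(params, drive) {
  stopifnot(inherits(params, "inverter_params"),
            inherits(drive, "oscillator_drive"))
  head_room <- drive$Vdd_osc - drive$Vin_osc
  if (head_room <= 4 * params$U_T) {
    stop("propagation_time: Eq. regime violated (headroom <= 4*U_T)")
  }
  I0 <- sqrt(params$I0_n * params$I0_p)
  kap <- (params$kappa_n + params$kappa_p) / 2
  params$C_out * head_room /
    (2 * I0 * exp((kap * drive$Vdd_osc - drive$Vin_osc) / params$U_T))
}

#' Numerical transition-time oracle
#'
#' Integrates the subthreshold node equation
#' \deqn{C_{out}\,\dot V_{out} = -I_{0}\,
#'   e^{(\kappa V_g - V_{in})/U_T} (1 - e^{-(V_{out}-V_{in})/U_T})}
#' (or its charging mirror) with an adaptive stiff-capable integrator until
#' the output crosses the halfway point, serving as independent ground truth
#' for the closed forms.
#'
#' @inheritParams discharge_time
#' @param direction `"fall"` or `"rise"`.
#' @param rtol Relative integration tolerance.
#' @return Halfway-crossing time in seconds.
#' @export
ode_transition_oracle <- function(params, drive, direction = c("fall", "rise"),
                                  rtol = 1e-8) {
  direction <- match.arg(direction)
  stopifnot(inherits(params, "inverter_params"),
            inherits(drive, "oscillator_drive"))

  if (direction == "fall") {
    if (drive$V_initial <= drive$Vin_osc) {
      stop("ode_transition_oracle: V_initial must exceed Vin_osc for fall")
    }
    if (drive$Vg <= drive$Vin_osc) {
      stop("ode_transition_oracle: did not converge; pull-down device is ",
           "off (Vg at or below the lower rail) so the transition time ",
           "diverges")
    }
    i_on <- params$I0_n *
      exp((params$kappa_n * drive$Vg - drive$Vin_osc) / params$U_T)
    target <- (drive$V_initial + drive$Vin_osc) / 2
    deriv <- function(t, y, parms) {
      list(-i_on / params$C_out *
             (1 - exp(-(y - drive$Vin_osc) / params$U_T)))
    }
    guess <- discharge_guess <- params$C_out * params$U_T / i_on *
      max((drive$V_initial - drive$Vin_osc) / params$U_T, 1)
  } else {
    if (drive$V_initial >= drive$Vdd_osc) {
      stop("ode_transition_oracle: V_initial must be below Vdd_osc for rise")
    }
    if (drive$Vg >= drive$Vdd_osc) {
      stop("ode_transition_oracle: did not converge; pull-up device is ",
           "off (Vg at or above the upper rail) so the transition time ",
           "diverges")
    }
    i_on <- params$I0_p *
      exp(params$kappa_p * (drive$Vdd_osc - drive$Vg) / params$U_T)
    target <- (drive$V_initial + drive$Vdd_osc) / 2
    deriv <- function(t, y, parms) {
      list(i_on / params$C_out *
             (1 - exp(-(drive$Vdd_osc - y) / params$U_T)))
    }
    guess <- params$C_out * params$U_T / i_on *
      max((drive$Vdd_osc - drive$V_initial) / params$U_T, 1)
  }

  root <- function(t, y, parms) y - target
  t_max <- guess * 1e4
  sol <- deSolve::lsodar(
    y = drive$V_initial, times = c(0, t_max), func = deriv,
    rootfunc = root, rtol = rtol, atol = rtol * abs(drive$Vdd_osc)
  )
  t_root <- attr(sol, "troot")
  if (is.null(t_root) || length(t_root) == 0) {
    stop("ode_transition_oracle: integration did not reach the halfway ",
         "point within ", signif(t_max, 3), " s (drive current ~",
         signif(i_on, 3), " A); the device may be off")
  }
  t_root[1]
}

#' Ring-oscillator frequency
#'
#' Oscillation frequency of an `n_stages` ring under the standard relation
#' `f = 1 / (2 * n_stages * t_P)`, with `t_P` from [propagation_time()].
#' Because `t_P` depends exponentially on the lower rail, so does `f`.
#'
#' @inheritParams discharge_time
#' @return Frequency in Hz.
#' @export
ring_frequency <- function(params, drive) {
  t_p <- propagation_time(params, drive)
  1 / (2 * drive$n_stages * t_p)
}

#' Frequency-transient calibration
#'
#' Exponential map from the synapse gate variable to the instantaneous
#' ring-oscillator frequency. While the gate discharges linearly the
#' oscillator frequency therefore decays exponentially, until the gate drops
#' below `gate_floor` (the saturation condition of the discharge device),
#' below which there is insufficient rail headroom and the oscillator is off.
#'
#' @param f_unit Frequency scale at zero gate, in Hz.
#' @param V_f Exponential gate-to-frequency scale, in V.
#' @param gate_floor Gate value below which the oscillator is off, in V.
#' @return An object of class `freq_calibration`.
#' @export
freq_calibration <- function(f_unit = 2332.7, V_f = 0.3504,
                             gate_floor = 0.005) {
  stopifnot(f_unit > 0, V_f > 0, gate_floor >= 0)
  structure(list(f_unit = f_unit, V_f = V_f, gate_floor = gate_floor),
            class = "freq_calibration")
}

#' Instantaneous oscillator frequency from a gate trace
#'
#' Maps a time series of the synapse gate variable to the instantaneous
#' oscillation frequency: `f = f_unit * exp(V_gate / V_f)` while the gate is
#' above `gate_floor`, and 0 (oscillator off) otherwise.
#'
#' @param gate_trace A data frame with columns `time` (s) and `V_gate` (V).
#' @param calibration A [freq_calibration()] object.
#' @return A tibble with columns `time` and `frequency` (Hz).
#' @export
frequency_transient_from_gate <- function(gate_trace,
                                          calibration = freq_calibration()) {
  stopifnot(is.data.frame(gate_trace),
            all(c("time", "V_gate") %in% names(gate_trace)),
            inherits(calibration, "freq_calibration"))
  v <- gate_trace$V_gate
  if (any(v < 0)) stop("gate trace must be non-negative")
  f <- ifelse(v > calibration$gate_floor,
              calibration$f_unit * exp(v / calibration$V_f), 0)
  tibble::tibble(time = gate_trace$time, frequency = f)
}

#' Closed-form vs oracle validation table
#'
#' Evaluates [discharge_time()], [charge_time()] and
#' [ode_transition_oracle()] over a random grid of drive conditions inside
#' the subthreshold regime, returning the relative error of each closed form
#' against the numerical oracle.
#'
#' @param params An [inverter_params()] object.
#' @param n Number of random grid points.
#' @param seed Random seed for the grid.
#' @return A tibble with one row per (point, direction).
#' @export
validate_oscillator <- function(params = inverter_params(), n = 25,
                                seed = 1L) {
  set.seed(seed)
  rows <- purrr::map_dfr(seq_len(n), function(i) {
    Vdd <- stats::runif(1, 0.4, 0.8)
    Vin <- stats::runif(1, 0.02, Vdd - 5 * params$U_T)
    drive_f <- oscillator_drive(Vdd_osc = Vdd, Vin_osc = Vin,
                                Vg = Vdd, V_initial = Vdd)
    drive_r <- oscillator_drive(Vdd_osc = Vdd, Vin_osc = Vin,
                                Vg = Vin, V_initial = Vin)
    t_f <- discharge_time(params, drive_f)
    o_f <- ode_transition_oracle(params, drive_f, "fall")
    t_r <- charge_time(params, drive_r)
    o_r <- ode_transition_oracle(params, drive_r, "rise")
    tibble::tibble(
      Vdd_osc = Vdd, Vin_osc = Vin,
      direction = c("fall", "rise"),
      closed_form = c(t_f, t_r),
      oracle = c(o_f, o_r),
      rel_error = abs(closed_form - oracle) / oracle
    )
  })
  rows
}
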