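#' Adaptive rectangular STDP parameters
#'
#' Rectangular spike-timing-dependent plasticity on four-bit efficacies:
#' a postsynaptic spike at `t_i` potentiates (+1) every synapse whose most
#' recent presynaptic spike `t_j` satisfies `t_j <= t_i` and
#' `t_i - t_j < t_pre`; a presynaptic spike at `t_j` depresses (-1) its
#' synapse when the most recent postsynaptic spike satisfies `t_j > t_i` and
#' `t_j - t_i < t_post`. The depression window `t_post` follows a
#' non-decreasing schedule of elapsed learning time (the adaptive part),
#' while `t_pre` stays fixed. Updates saturate at `w_min`/`w_max`.
#'
#' The default schedule (linear 5 ms to 40 ms over the first 150 s, then
#' constant) is a calibration: the hardware controls the windows by external
#' bias voltages whose quantitative mapping is not part of the behavioral
#' model. It is chosen so that early learning is potentiation-dominated
#' (output rate settles in the tens-of-Hz band) and late learning prunes
#' pattern-uncorrelated afferents.
#'
#' @param t_pre Potentiation window, s.
#' @param schedule `"constant"`, `"linear"`, `"piecewise"`, or a function
#'   `f(t_elapsed) -> t_post` (must be non-decreasing).
#' @param t_post0 Initial depression window, s.
#' @param t_post_max Final depression window (linear schedule), s.
#' @param t_ramp Ramp duration of the linear schedule, s.
#' @param knot_times,knot_values Knots of the piecewise-linear schedule
#'   (times in s, non-decreasing window values in s); used when
#'   `schedule = "piecewise"`.
#' @param w_min,w_max Efficacy bounds (four-bit: 0 and 15).
#' @return An object of class `learning_params`.
#' @export
learning_params <- function(t_pre = 0.015,
                            schedule = c("linear", "constant", "piecewise"),
                            t_post0 = 0.005, t_post_max = 0.040,
                            t_ramp = 150,
                            knot_times = c(0, t_ramp),
                            knot_values = c(t_post0, t_post_max),
                            w_min = 0L, w_max = 15L) {
  stopifnot(t_pre > 0, t_post0 >= 0, t_post_max >= t_post0, t_ramp > 0,
            w_min < w_max)
  if (is.function(schedule)) {
    sched_fun <- schedule
    sched_name <- "custom"
  } else {
    sched_name <- match.arg(schedule)
    sched_fun <- NULL
  }
  stopifnot(length(knot_times) == length(knot_values),
            length(knot_times) >= 1,
            !is.unsorted(knot_times), !is.unsorted(knot_values))
  structure(
    list(t_pre = t_pre, schedule = sched_name, schedule_fun = sched_fun,
         t_post0 = t_post0, t_post_max = t_post_max, t_ramp = t_ramp,
         knot_times = knot_times, knot_values = knot_values,
         w_min = as.integer(w_min), w_max = as.integer(w_max)),
    class = "learning_params"
  )
}

# schedule as (times, values) knots for the simulation core
.schedule_knots <- function(params) {
  switch(params$schedule,
    constant = list(t = 0, v = params$t_post0),
    linear = list(t = c(0, params$t_ramp),
                  v = c(params$t_post0, params$t_post_max)),
    piecewise = list(t = params$knot_times, v = params$knot_values),
    custom = {
      tt <- seq(0, 300, by = 0.5)
      list(t = tt, v = vapply(tt, params$schedule_fun, numeric(1)))
    }
  )
}

#' Depression window at a given elapsed learning time
#'
#' @param t_elapsed Elapsed learning time, s (>= 0).
#' @param params A [learning_params()].
#' @return The depression window `t_post`, s.
#' @export
t_post_at <- function(t_elapsed, params) {
  stopifnot(all(t_elapsed >= 0), inherits(params, "learning_params"))
  switch(params$schedule,
    constant = rep(params$t_post0, length(t_elapsed)),
    linear = params$t_post0 +
      (params$t_post_max - params$t_post0) *
        pmin(t_elapsed / params$t_ramp, 1),
    piecewise = stats::approx(params$knot_times, params$knot_values,
                              xout = t_elapsed, rule = 2)$y,
    custom = vapply(t_elapsed, params$schedule_fun, numeric(1))
  )
}

#' Per-synapse learning state
#'
#' Nearest-spike memory: each synapse remembers only its most recent
#' presynaptic spike, and one shared most recent postsynaptic spike time is
#' kept (the learning circuit holds a single timing capacitor per synapse).
#'
#' @param n_syn Number of synapses.
#' @param w0 Initial efficacy (scalar or length `n_syn`).
#' @param params A [learning_params()].
#' @return An object of class `learning_state` with fields `w`, `last_pre`
#'   (NA when no pre spike seen), `last_post` (NA), and `last_event` (for
#'   ordering checks).
#' @export
learning_state <- function(n_syn, w0 = 8L, params = learning_params()) {
  w <- as.integer(rep_len(w0, n_syn))
  stopifnot(all(w >= params$w_min), all(w <= params$w_max))
  structure(
    list(w = w, last_pre = rep(NA_real_, n_syn), last_post = NA_real_,
         last_event = -Inf, params = params),
    class = "learning_state"
  )
}

.check_order <- function(state, t) {
  if (t < state$last_event) {
    stop("plasticity: out-of-order event at t = ", t,
         " (last processed ", state$last_event, ")")
  }
}

#' Process a postsynaptic spike (potentiation)
#'
#' Every synapse whose remembered presynaptic spike lies within `t_pre`
#' before (or exactly at) `t_i` increments by one bit, saturating at
#' `w_max`; at most one increment per synapse per postsynaptic spike.
#'
#' @param state A [learning_state()].
#' @param t_i Postsynaptic spike time, s; must not precede previously
#'   processed events.
#' @return The updated state.
#' @export
on_post_spike <- function(state, t_i) {
  stopifnot(inherits(state, "learning_state"))
  .check_order(state, t_i)
  p <- state$params
  eligible <- !is.na(state$last_pre) &
    state$last_pre <= t_i &
    (t_i - state$last_pre) < p$t_pre &
    state$w < p$w_max
  state$w[eligible] <- state$w[eligible] + 1L
  state$last_post <- t_i
  state$last_event <- t_i
  state
}

#' Process a presynaptic spike (depression)
#'
#' The spiking synapse decrements by one bit if the most recent
#' postsynaptic spike happened strictly before `t_j` and within the current
#' depression window `t_post(t_elapsed)`, saturating at `w_min`. The
#' synapse's presynaptic memory is then updated. At equal pre/post
#' timestamps the potentiation branch applies, never depression.
#'
#' @param state A [learning_state()].
#' @param syn Index of the spiking synapse.
#' @param t_j Presynaptic spike time, s.
#' @param t_elapsed Elapsed learning time used by the `t_post` schedule, s;
#'   defaults to `t_j`.
#' @return The updated state.
#' @export
on_pre_spike <- function(state, syn, t_j, t_elapsed = t_j) {
  stopifnot(inherits(state, "learning_state"),
            syn >= 1, syn <= length(state$w))
  .check_order(state, t_j)
  p <- state$params
  t_post <- t_post_at(t_elapsed, p)
  if (!is.na(state$last_post) &&
      t_j > state$last_post &&
      (t_j - state$last_post) < t_post &&
      state$w[syn] > p$w_min) {
    state$w[syn] <- state$w[syn] - 1L
  }
  state$last_pre[syn] <- t_j
  state$last_event <- t_j
  state
}

#' Replay a pre/post event stream through the STDP rule
#'
#' Event-driven application of the learning rule to a full stream of
#' presynaptic and postsynaptic events. Events are processed in time order;
#' at equal timestamps presynaptic events are processed first so that the
#' potentiation branch sees simultaneous pairs.
#'
#' @param events A data frame with columns `time`, `type`
#'   (`"pre"`/`"post"`), and `syn` (synapse index; ignored for post events).
#' @param n_syn Number of synapses.
#' @param w0 Initial efficacy.
#' @param params A [learning_params()].
#' @return The final [learning_state()].
#' @export
stdp_apply_events <- function(events, n_syn, w0 = 8L,
                              params = learning_params()) {
  stopifnot(is.data.frame(events),
            all(c("time", "type") %in% names(events)))
  pre_first <- order(events$time, events$type != "pre")
  events <- events[pre_first, , drop = FALSE]
  state <- learning_state(n_syn, w0, params)
  for (i in seq_len(nrow(events))) {
    if (events$type[i] == "pre") {
      state <- on_pre_spike(state, events$syn[i], events$time[i])
    } else {
      state <- on_post_spike(state, events$time[i])
    }
  }
  state
}
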