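#' Run the spike-pattern detection experiment
#'
#' Wires one synapse circuit per afferent to the single-compartment
#' (conveyor-clamped) neuron and simulates the full train with a fixed-step
#' loop: every afferent spike triggers the DAC input pulse on its synapse
#' and the depression branch of the learning rule; every soma spike
#' triggers the potentiation branch on all synapses. Because the
#' postsynaptic node is clamped, each synapse's current is its conductance
#' times a constant driving factor set by its mode.
#'
#' @param ts A [spike_train_set] (one synapse per afferent).
#' @param network A [network_config()] in single-compartment mode.
#' @param learning A [learning_params()]; `NULL` freezes the efficacies.
#' @param synapse A [synapse_config()] shared by all synapses.
#' @param mode Synaptic output mode: `"smooth"` (conductance-based, smooth
#'   current), `"oscillatory"` (conductance-based, charge packets gated by
#'   the ring oscillator), or `"excitatory_current"` (current-based).
#' @param w0 Initial efficacy (scalar or per-synapse).
#' @param dt Integration step, s.
#' @param snapshot_every Efficacy snapshot interval, s (0 disables).
#' @return An object of class `detection_result`.
#' @export
run_detection <- function(ts, network = network_config(),
                          learning = learning_params(),
                          synapse = synapse_config(),
                          mode = c("oscillatory", "smooth",
                                   "excitatory_current"),
                          w0 = 8L, dt = 1e-4, snapshot_every = 5) {
  mode <- match.arg(mode)
  stopifnot(inherits(ts, "spike_train_set"),
            inherits(network, "network_config"),
            inherits(synapse, "synapse_config"))
  if (network$configuration != "single_compartment") {
    stop("run_detection: the detection experiment uses the ",
         "single-compartment configuration")
  }
  cfg <- ts$config
  learn <- !is.null(learning)
  if (!learn) learning <- learning_params()

  drive <- switch(mode,
    oscillatory = ,
    smooth = phi_iv(synapse$E_syn - network$V_post_clamp,
                    synapse$V_alpha, synapse$V_beta),
    excitatory_current = synapse$s_exc
  )
  sp <- ts$spikes[order(ts$spikes$time), ]
  soma <- network$soma

  raw <- sim_detect_cpp(
    ev_aff = sp$afferent - 1L, ev_time = sp$time,
    n_aff = cfg$n_aff, duration = cfg$duration, dt = dt,
    charge_rate = synapse$charge_rate,
    discharge_rate = synapse$discharge_rate,
    gate_floor = synapse$gate_floor, gate_max = synapse$gate_max,
    pulse_width = synapse$pulse_width,
    g_unit = synapse$g_unit, ut_eff = synapse$U_T_eff, drive = drive,
    oscillatory = (mode == "oscillatory"),
    f_unit = synapse$freq$f_unit, v_f = synapse$freq$V_f,
    duty = synapse$duty,
    c_mem = soma$C_mem, g_leak = soma$g_leak, v_rest = soma$V_rest,
    v_thresh = soma$V_thresh, v_reset = soma$V_reset,
    t_refr = soma$t_refr,
    learn = learn, t_pre = learning$t_pre,
    sched_t = .schedule_knots(learning)$t,
    sched_v = .schedule_knots(learning)$v,
    w0 = as.integer(rep_len(w0, cfg$n_aff)),
    w_min = learning$w_min, w_max = learning$w_max,
    snapshot_every = snapshot_every
  )

  n_snap <- length(raw$snapshot_times)
  weight_trace <- if (n_snap > 0) {
    tibble::tibble(
      time = rep(raw$snapshot_times, each = cfg$n_aff),
      afferent = rep(seq_len(cfg$n_aff), times = n_snap),
      w = raw$snapshot_w
    )
  } else {
    tibble::tibble(time = numeric(0), afferent = integer(0), w = integer(0))
  }

  res <- structure(
    list(
      post_spike_times = raw$post_spike_times,
      final_weights = raw$final_w,
      weight_trace = weight_trace,
      t_post_trace = tibble::tibble(time = raw$snapshot_times,
                                    t_post = raw$snapshot_t_post),
      occurrences = ts$occurrences,
      duration = cfg$duration,
      section = cfg$section,
      mode = mode
    ),
    class = "detection_result"
  )
  score_detection(res)
}

#' Score hits and false alarms
#'
#' Scores post-spike times against pattern occurrences within an evaluation
#' window at the end of the run: a hit is an occurrence (lying fully inside
#' the window) whose 50 ms interval contains at least one soma spike; a
#' false alarm is a soma spike in the window outside every occurrence
#' interval. Occurrences truncated by the window edge are excluded from
#' both accountings.
#'
#' @param post_times Sorted soma spike times, s.
#' @param occurrences Occurrence start times, s.
#' @param t_start,t_end Evaluation window, s.
#' @param section Occurrence length, s.
#' @return A list with `hits`, `n_occurrences`, `hit_rate` (percent; NA if
#'   the window holds no occurrence), `false_alarms`, and `degenerate`.
#' @export
detection_score <- function(post_times, occurrences, t_start, t_end,
                            section = 0.05) {
  occ <- occurrences[occurrences >= t_start & occurrences + section <= t_end]
  in_win <- post_times[post_times >= t_start & post_times <= t_end]
  if (length(occ) == 0) {
    return(list(hits = 0L, n_occurrences = 0L, hit_rate = NA_real_,
                false_alarms = NA_integer_, degenerate = TRUE))
  }
  idx <- findInterval(in_win, occ)
  covered <- idx >= 1 & in_win < occ[pmax(idx, 1)] + section
  hits <- length(unique(idx[covered]))
  # spikes inside a truncated occurrence (outside `occ`) are excluded too
  all_idx <- findInterval(in_win, occurrences)
  in_any_occ <- all_idx >= 1 &
    in_win < occurrences[pmax(all_idx, 1)] + section
  list(
    hits = hits,
    n_occurrences = length(occ),
    hit_rate = 100 * hits / length(occ),
    false_alarms = sum(!in_any_occ),
    degenerate = FALSE
  )
}

#' Score a detection result over its final window
#'
#' @param res A `detection_result`.
#' @param window Length of the evaluation window at the end of the run, s.
#' @return The result with `hits`, `hit_rate`, `false_alarms`, and
#'   `success` fields populated.
#' @export
score_detection <- function(res, window = 75) {
  stopifnot(inherits(res, "detection_result"))
  sc <- detection_score(res$post_spike_times, res$occurrences,
                        t_start = res$duration - window,
                        t_end = res$duration, section = res$section)
  res$hits <- sc$hits
  res$n_occurrences_window <- sc$n_occurrences
  res$hit_rate <- sc$hit_rate
  res$false_alarms <- sc$false_alarms
  res$degenerate <- sc$degenerate
  res$success <- detection_success(sc$hit_rate, sc$false_alarms)
  res
}

#' Detection success criterion
#'
#' Success requires a hit rate strictly greater than 98 percent and zero
#' false alarms in the evaluation window.
#'
#' @param hit_rate Hit rate, percent.
#' @param false_alarms False-alarm count.
#' @return TRUE or FALSE (FALSE for a degenerate window).
#' @export
detection_success <- function(hit_rate, false_alarms) {
  if (is.na(hit_rate) || is.na(false_alarms)) return(FALSE)
  hit_rate > 98 && false_alarms == 0
}

#' Output rate over an initial segment of the run
#'
#' @param res A `detection_result`.
#' @param t_first Segment length, s.
#' @return Mean soma spike rate, Hz.
#' @export
initial_output_rate <- function(res, t_first = 5) {
  sum(res$post_spike_times < t_first) / t_first
}

#' @export
print.detection_result <- function(x, ...) {
  cat("<detection_result> mode=", x$mode, ": ",
      length(x$post_spike_times), " soma spikes over ", x$duration,
      " s\n  final 75 s: hit rate ",
      if (is.na(x$hit_rate)) "NA" else sprintf("%.1f%%", x$hit_rate),
      " (", x$hits, "/", x$n_occurrences_window, "), ",
      x$false_alarms, " false alarms -> ",
      if (x$success) "SUCCESS" else "failure", "\n", sep = "")
  invisible(x)
}

#' Batch of detection runs
#'
#' Runs the full experiment on independently generated stimuli, one seed
#' per run, and aggregates the success rate.
#'
#' @param cfg A [task_config()].
#' @param network,learning,synapse,mode,w0,dt Passed to [run_detection()].
#' @param n_runs Number of runs.
#' @param seed_base Base seed; run `r` uses `seed_base + r - 1`.
#' @return An object of class `detection_batch` with a per-run tibble
#'   (`$runs`) and the aggregate `$success_rate` (percent).
#' @export
run_batch <- function(cfg = task_config(), network = network_config(),
                      learning = learning_params(),
                      synapse = synapse_config(),
                      mode = "oscillatory", w0 = 8L, dt = 1e-4,
                      n_runs = 50, seed_base = 1L) {
  stopifnot(n_runs >= 1)
  rows <- purrr::map_dfr(seq_len(n_runs), function(r) {
    seed <- seed_base + r - 1L
    ts <- generate_spike_trains(cfg, seed = seed)
    res <- run_detection(ts, network, learning, synapse, mode = mode,
                         w0 = w0, dt = dt, snapshot_every = 0)
    tibble::tibble(
      run = r, seed = seed,
      n_post = length(res$post_spike_times),
      initial_rate = initial_output_rate(res),
      hit_rate = res$hit_rate,
      false_alarms = res$false_alarms,
      weights_extreme = mean(res$final_weights %in% c(0L, 15L)),
      success = res$success
    )
  })
  structure(
    list(runs = rows,
         success_rate = 100 * mean(rows$success),
         mode = mode, repeat_fraction = cfg$repeat_fraction),
    class = "detection_batch"
  )
}

#' Paired comparison of oscillatory and smooth output modes
#'
#' Runs the experiment in both conductance-based output modes on identical
#' stimuli (same seeds), for paired analysis of the success indicators
#' (e.g. a McNemar test of marginal homogeneity).
#'
#' @inheritParams run_batch
#' @param n_pairs Number of paired seeds.
#' @return A tibble with one row per seed and logical columns
#'   `success_oscillatory`, `success_smooth`.
#' @export
compare_modes <- function(cfg = task_config(), network = network_config(),
                          learning = learning_params(),
                          synapse = synapse_config(), w0 = 8L, dt = 1e-4,
                          n_pairs = 20, seed_base = 1L) {
  purrr::map_dfr(seq_len(n_pairs), function(r) {
    seed <- seed_base + r - 1L
    ts <- generate_spike_trains(cfg, seed = seed)
    r_osc <- run_detection(ts, network, learning, synapse,
                           mode = "oscillatory", w0 = w0, dt = dt,
                           snapshot_every = 0)
    r_smooth <- run_detection(ts, network, learning, synapse,
                              mode = "smooth", w0 = w0, dt = dt,
                              snapshot_every = 0)
    tibble::tibble(seed = seed,
                   success_oscillatory = r_osc$success,
                   success_smooth = r_smooth$success)
  })
}

#' @export
print.detection_batch <- function(x, ...) {
  cat("<detection_batch> ", nrow(x$runs), " runs, mode=", x$mode,
      ", repeat fraction ", x$repeat_fraction, ": success rate ",
      sprintf("%.0f%%", x$success_rate), "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy detection_result
#' @export
tidy.detection_result <- function(x, ...) {
  tibble::tibble(afferent = seq_along(x$final_weights),
                 w = x$final_weights)
}

#' @method glance detection_result
#' @export
glance.detection_result <- function(x, ...) {
  tibble::tibble(
    n_post = length(x$post_spike_times),
    hits = x$hits,
    n_occurrences_window = x$n_occurrences_window,
    hit_rate = x$hit_rate,
    false_alarms = x$false_alarms,
    success = x$success,
    mode = x$mode
  )
}

#' @method tidy detection_batch
#' @export
tidy.detection_batch <- function(x, ...) x$runs

#' @method glance detection_batch
#' @export
glance.detection_batch <- function(x, ...) {
  tibble::tibble(
    n_runs = nrow(x$runs),
    success_rate = x$success_rate,
    mean_hit_rate = mean(x$runs$hit_rate, na.rm = TRUE),
    mean_initial_rate = mean(x$runs$initial_rate),
    mode = x$mode,
    repeat_fraction = x$repeat_fraction
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Final-efficacy histogram of a detection run
#'
#' After successful pattern learning the efficacies split into a bimodal
#' distribution with modes at the two saturation values.
#'
#' @param object A `detection_result`.
#' @param ... Unused.
#' @method autoplot detection_result
#' @export
autoplot.detection_result <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$w)) +
    ggplot2::geom_bar() +
    ggplot2::scale_x_continuous(breaks = seq(0, 15, 3)) +
    ggplot2::labs(x = "synaptic efficacy (4-bit)", y = "synapses",
                  title = "Final efficacy distribution")
}

#' Raster plot of a spike-train window
#'
#' @param object A `spike_train_set`.
#' @param t_start,t_end Window to draw, s.
#' @param ... Unused.
#' @method autoplot spike_train_set
#' @export
autoplot.spike_train_set <- function(object, t_start = 0, t_end = 1, ...) {
  sp <- dplyr::filter(object$spikes,
                      .data$time >= t_start, .data$time <= t_end)
  occ <- object$occurrences
  occ <- occ[occ >= t_start - object$config$section & occ <= t_end]
  p <- ggplot2::ggplot(sp, ggplot2::aes(x = .data$time, y = .data$afferent)) +
    ggplot2::geom_point(shape = ".", alpha = 0.6) +
    ggplot2::labs(x = "time (s)", y = "afferent")
  if (length(occ) > 0) {
    shade <- tibble::tibble(xmin = occ, xmax = occ + object$config$section)
    p <- p + ggplot2::geom_rect(
      data = shade, inherit.aes = FALSE, alpha = 0.2, fill = "orange",
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -Inf, ymax = Inf))
  }
  p
}
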