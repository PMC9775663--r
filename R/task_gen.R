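#' Spike-pattern task configuration
#'
#' Configuration of the synthetic stimulus for the spike-pattern detection
#' task: independent afferents firing as inhomogeneous Poisson processes
#' whose instantaneous rate performs a slew-limited random walk in
#' `[rate_min, rate_max]`, a minimum-activity guarantee of at least one
#' spike per afferent per 50 ms window, and a repeated 50 ms pattern pasted
#' into a fraction of the 50 ms sections with no two consecutive
#' replacements.
#'
#' @param n_aff Number of afferents.
#' @param duration Train length, s; must be an integer multiple of
#'   `section`.
#' @param section Section length, s (the pattern length).
#' @param repeat_fraction Fraction of sections replaced by the pattern, in
#'   `[0, 0.5]` (above 0.5 a non-adjacent placement is infeasible).
#' @param rate_min,rate_max Instantaneous rate bounds, Hz.
#' @param slew_max Maximum rate change speed, Hz/s. The default
#'   `(rate_max - rate_min) / 0.05` means the rate cannot sweep its full
#'   range in under 50 ms.
#' @param min_activity_window Window guaranteeing at least one spike, s.
#' @param rate_dt Resolution of the piecewise-linear rate walk, s.
#' @return An object of class `task_config`.
#' @export
task_config <- function(n_aff = 256L, duration = 225, section = 0.05,
                        repeat_fraction = 0.25, rate_min = 0, rate_max = 90,
                        slew_max = (rate_max - rate_min) / 0.05,
                        min_activity_window = 0.05, rate_dt = 1e-3) {
  n_sections <- duration / section
  if (abs(n_sections - round(n_sections)) > 1e-9) {
    stop("task_config: duration must be an integer multiple of section")
  }
  if (repeat_fraction < 0 || repeat_fraction > 0.5) {
    stop("task_config: repeat_fraction must lie in [0, 0.5] ",
         "(non-consecutive placement is infeasible above 0.5)")
  }
  stopifnot(n_aff >= 1, rate_max > rate_min, rate_min >= 0, slew_max > 0,
            min_activity_window > 0, rate_dt > 0)
  structure(
    list(n_aff = as.integer(n_aff), duration = duration, section = section,
         n_sections = as.integer(round(n_sections)),
         repeat_fraction = repeat_fraction, rate_min = rate_min,
         rate_max = rate_max, slew_max = slew_max,
         min_activity_window = min_activity_window, rate_dt = rate_dt),
    class = "task_config"
  )
}

# Reflect a free walk into [lo, hi] (triangle fold; exact for step sizes
# smaller than the band width).
.reflect <- function(x, lo, hi) {
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  lo + span - abs(y - span)
}

#' Slew-limited random rate profiles
#'
#' Generates per-afferent instantaneous-rate time series: piecewise-linear
#' walks at resolution `rate_dt` with increments uniform in
#' `[-slew_max * rate_dt, +slew_max * rate_dt]`, reflected at the rate
#' bounds, started from the stationary (uniform) distribution.
#'
#' @param cfg A [task_config()].
#' @param n_aff Number of profiles to draw (defaults to `cfg$n_aff`).
#' @return A matrix with `duration / rate_dt + 1` rows (time samples,
#'   including both endpoints) and one column per afferent, in Hz.
#' @export
gen_rate_profiles <- function(cfg, n_aff = cfg$n_aff) {
  stopifnot(inherits(cfg, "task_config"))
  n_steps <- round(cfg$duration / cfg$rate_dt)
  step_max <- cfg$slew_max * cfg$rate_dt
  rate_walk_cpp(n_steps, n_aff, cfg$rate_min, cfg$rate_max, step_max)
}

#' Inhomogeneous Poisson spike sampling
#'
#' Thinning-based sampling: homogeneous candidates at `rate_max` are kept
#' with probability `r(t) / rate_max`, with `r(t)` evaluated by linear
#' interpolation of the piecewise-linear rate profile. Afferents are
#' independent.
#'
#' @param rates A rate matrix from [gen_rate_profiles()].
#' @param cfg A [task_config()].
#' @return A list of sorted spike-time vectors, one per column of `rates`.
#' @export
gen_poisson_spikes <- function(rates, cfg) {
  stopifnot(inherits(cfg, "task_config"), is.matrix(rates))
  lapply(seq_len(ncol(rates)), function(i) {
    n_cand <- stats::rpois(1, cfg$rate_max * cfg$duration)
    t_cand <- stats::runif(n_cand, 0, cfg$duration)
    r_cand <- .rate_at(rates[, i], t_cand, cfg$rate_dt)
    sort(t_cand[stats::runif(n_cand) < r_cand / cfg$rate_max])
  })
}

# Linear interpolation of a rate profile sampled on a uniform grid.
.rate_at <- function(profile, t, dt) {
  pos <- t / dt
  i <- pmin.int(floor(pos), length(profile) - 2)
  frac <- pos - i
  profile[i + 1] * (1 - frac) + profile[i + 2] * frac
}

#' Enforce the minimum-activity guarantee
#'
#' Every disjoint `min_activity_window` of every afferent must contain at
#' least one spike (a 20 Hz floor for 50 ms windows); windows left empty by
#' the Poisson draw receive one spike at a uniformly random position.
#'
#' @param trains A list of sorted spike-time vectors.
#' @param cfg A [task_config()].
#' @return The augmented list of sorted spike-time vectors.
#' @export
enforce_min_activity <- function(trains, cfg) {
  stopifnot(inherits(cfg, "task_config"))
  win <- cfg$min_activity_window
  n_win <- round(cfg$duration / win)
  lapply(trains, function(tt) {
    occupied <- unique(pmin(floor(tt / win), n_win - 1))
    missing <- setdiff(seq_len(n_win) - 1L, occupied)
    if (length(missing) == 0) return(tt)
    sort(c(tt, (missing + stats::runif(length(missing))) * win))
  })
}

#' Embed the repeated pattern into spike trains
#'
#' Chooses one random 50 ms section of the (already floored) trains as the
#' target pattern, then replaces `round(repeat_fraction * n_sections)`
#' sections -- drawn uniformly among all subsets with no two adjacent
#' sections -- with the pattern across every afferent. The source section
#' is one of the replaced sections by definition (its content already equals
#' the pattern) and counts as an occurrence.
#'
#' @param trains A list of sorted spike-time vectors (one per afferent).
#' @param cfg A [task_config()].
#' @return A [spike_train_set] object.
#' @export
embed_pattern <- function(trains, cfg) {
  stopifnot(inherits(cfg, "task_config"), length(trains) == cfg$n_aff)
  n_sec <- cfg$n_sections
  k <- round(cfg$repeat_fraction * n_sec)

  if (k == 0) {
    return(new_spike_train_set(trains, pattern = NULL,
                               occurrences = numeric(0), cfg = cfg))
  }
  # Uniform non-adjacent k-subset of 1..n_sec via the gap bijection.
  q <- sort(sample.int(n_sec - k + 1, k))
  sections <- q + seq_len(k) - 1L
  source_sec <- sections[sample.int(k, 1)]

  src_lo <- (source_sec - 1) * cfg$section
  pattern <- lapply(trains, function(tt) {
    tt[tt >= src_lo & tt < src_lo + cfg$section] - src_lo
  })

  in_replaced <- function(tt) {
    sec_id <- pmin(floor(tt / cfg$section) + 1, n_sec)
    sec_id %in% sections
  }
  starts <- (sections - 1) * cfg$section
  new_trains <- purrr::map2(trains, pattern, function(tt, off) {
    kept <- tt[!in_replaced(tt)]
    pasted <- rep(starts, each = length(off)) + rep(off, times = length(starts))
    sort(c(kept, pasted))
  })
  new_spike_train_set(new_trains, pattern = pattern,
                      occurrences = starts, cfg = cfg)
}

#' Spike-train set
#'
#' The detection experiment's input: per-afferent spike times, the embedded
#' 50 ms pattern, and the sorted start times of its occurrences.
#'
#' @param trains List of sorted per-afferent spike-time vectors.
#' @param pattern List of per-afferent pattern offsets in `[0, section)`,
#'   or NULL when no pattern is embedded.
#' @param occurrences Sorted occurrence start times, s.
#' @param cfg The generating [task_config()].
#' @return An object of class `spike_train_set` with elements `spikes`
#'   (a tibble with columns `afferent`, `time`), `pattern` (a tibble with
#'   `afferent`, `offset`), `occurrences`, and `config`.
#' @export
new_spike_train_set <- function(trains, pattern, occurrences, cfg) {
  spikes <- tibble::tibble(
    afferent = rep.int(seq_along(trains), lengths(trains)),
    time = unlist(trains, use.names = FALSE)
  )
  pat <- if (is.null(pattern)) {
    tibble::tibble(afferent = integer(0), offset = numeric(0))
  } else {
    tibble::tibble(
      afferent = rep.int(seq_along(pattern), lengths(pattern)),
      offset = unlist(pattern, use.names = FALSE)
    )
  }
  structure(
    list(spikes = spikes, pattern = pat,
         occurrences = sort(occurrences), config = cfg),
    class = "spike_train_set"
  )
}

#' @export
print.spike_train_set <- function(x, ...) {
  cfg <- x$config
  cat("<spike_train_set> ", cfg$n_aff, " afferents, ", cfg$duration,
      " s, ", nrow(x$spikes), " spikes, ", length(x$occurrences),
      " pattern occurrences\n", sep = "")
  invisible(x)
}

# Per-afferent list-of-vectors view of the spikes tibble.
spike_train_list <- function(ts) {
  stopifnot(inherits(ts, "spike_train_set"))
  out <- vector("list", ts$config$n_aff)
  sp <- split(ts$spikes$time, factor(ts$spikes$afferent,
                                     levels = seq_len(ts$config$n_aff)))
  for (i in seq_along(sp)) out[[i]] <- sp[[i]]
  out
}

#' Generate a complete task stimulus
#'
#' Full pipeline: slew-limited rate walks, inhomogeneous Poisson sampling,
#' minimum-activity floor, pattern embedding. Afferents are processed in
#' chunks so the rate profiles are never all materialized.
#'
#' @param cfg A [task_config()].
#' @param seed Optional random seed.
#' @return A [spike_train_set] object.
#' @export
generate_spike_trains <- function(cfg = task_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chunk <- 16L
  trains <- vector("list", cfg$n_aff)
  for (lo in seq(1L, cfg$n_aff, by = chunk)) {
    hi <- min(lo + chunk - 1L, cfg$n_aff)
    rates <- gen_rate_profiles(cfg, n_aff = hi - lo + 1L)
    trains[lo:hi] <- gen_poisson_spikes(rates, cfg)
  }
  trains <- enforce_min_activity(trains, cfg)
  embed_pattern(trains, cfg)
}

#' Population rate inside vs outside the pattern
#'
#' Mean per-afferent spike rate measured in short time bins, partitioned by
#' bins inside vs outside pattern occurrences. By construction of the task
#' the two should agree: the pattern is hidden in the population rate and
#' distinguishable only by spike timing.
#'
#' @param ts A [spike_train_set] object.
#' @param bin Bin width, s (must divide the section length).
#' @return A tibble with columns `rate_inside`, `rate_outside` (Hz;
#'   `rate_inside` is NA with a `degenerate` flag when there are no
#'   occurrences), and the bin counts.
#' @export
population_rate_stats <- function(ts, bin = 0.01) {
  stopifnot(inherits(ts, "spike_train_set"), bin > 0)
  cfg <- ts$config
  n_bins <- round(cfg$duration / bin)
  bin_id <- pmin(floor(ts$spikes$time / bin), n_bins - 1)
  counts <- tabulate(bin_id + 1L, nbins = n_bins)

  bins_per_sec <- round(cfg$section / bin)
  inside <- rep(FALSE, n_bins)
  for (s in ts$occurrences) {
    b0 <- round(s / bin)
    inside[(b0 + 1):(b0 + bins_per_sec)] <- TRUE
  }
  denom <- function(nb) nb * bin * cfg$n_aff
  degenerate <- !any(inside)
  tibble::tibble(
    rate_inside = if (degenerate) NA_real_ else
      sum(counts[inside]) / denom(sum(inside)),
    rate_outside = sum(counts[!inside]) / denom(sum(!inside)),
    n_bins_inside = sum(inside),
    n_bins_outside = sum(!inside),
    degenerate = degenerate
  )
}
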