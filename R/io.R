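#' Write spike trains to a plain-text event file
#'
#' Tab-separated, one event per line (`afferent_id<TAB>time_seconds`,
#' afferent ids 0-based), sorted by time, with the header line
#' `# shuntsim-spikes v1 n_aff=<N> duration=<T>`. Times are quantized to
#' 1 microsecond on disk. If the set has pattern occurrences they are
#' written alongside as `<path>.occurrences` (one start time per line).
#'
#' @param ts A [spike_train_set] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spike_trains <- function(ts, path) {
  stopifnot(inherits(ts, "spike_train_set"))
  cfg <- ts$config
  sp <- ts$spikes[order(ts$spikes$time, ts$spikes$afferent), ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# shuntsim-spikes v1 n_aff=%d duration=%s",
                     cfg$n_aff, format(cfg$duration)), con)
  writeLines(sprintf("%d\t%.6f", sp$afferent - 1L, sp$time), con)
  if (length(ts$occurrences) > 0) {
    writeLines(sprintf("%.6f", ts$occurrences),
               paste0(path, ".occurrences"))
  }
  invisible(path)
}

#' Read spike trains from a plain-text event file
#'
#' Inverse of [write_spike_trains()] (without pattern information unless
#' the companion `.occurrences` file is present). Validates the v1 header,
#' afferent id bounds, and per-afferent time ordering.
#'
#' @param path Input file path.
#' @return A [spike_train_set] object (empty pattern).
#' @export
read_spike_trains <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 ||
      !grepl("^# shuntsim-spikes v1 n_aff=\\d+ duration=", lines[1])) {
    stop("read_spike_trains: missing or malformed v1 header in ", path)
  }
  n_aff <- as.integer(sub("^.*n_aff=(\\d+).*$", "\\1", lines[1]))
  duration <- as.numeric(sub("^.*duration=([0-9.eE+-]+)\\s*$", "\\1",
                             lines[1]))
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) > 0) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 2)
    if (length(bad) > 0) {
      stop("read_spike_trains: malformed line ", bad[1] + 1L, " in ", path)
    }
    aff <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 1)))
    tt <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2)))
    if (anyNA(aff) || anyNA(tt)) {
      stop("read_spike_trains: non-numeric field at line ",
           which(is.na(aff) | is.na(tt))[1] + 1L, " in ", path)
    }
    if (any(aff < 0 | aff >= n_aff)) {
      stop("read_spike_trains: afferent id out of [0, n_aff) at line ",
           which(aff < 0 | aff >= n_aff)[1] + 1L)
    }
    if (is.unsorted(tt)) {
      stop("read_spike_trains: events are not sorted by time")
    }
  } else {
    aff <- integer(0)
    tt <- numeric(0)
  }
  # events closer than the 1 us disk resolution merge on the round trip
  trains <- lapply(seq_len(n_aff) - 1L, function(a) unique(sort(tt[aff == a])))
  cfg <- task_config(n_aff = n_aff, duration = duration,
                     repeat_fraction = 0)
  occ_path <- paste0(path, ".occurrences")
  occurrences <- if (file.exists(occ_path)) {
    as.numeric(readLines(occ_path))
  } else {
    numeric(0)
  }
  new_spike_train_set(trains, pattern = NULL, occurrences = occurrences,
                      cfg = cfg)
}

# Default configuration tree mirroring the constructors' defaults.
.default_config <- function() {
  list(
    task = list(n_aff = 256L, duration = 225, section = 0.05,
                repeat_fraction = 0.25, rate_min = 0, rate_max = 90,
                min_activity_window = 0.05),
    synapse = list(mode = "conductance", E_syn = 50, charge_rate = 25,
                   discharge_rate = 20, gate_floor = 0.005,
                   pulse_width = 2e-3, g_unit = 2e-6, U_T_eff = 0.09,
                   V_alpha = 25, V_beta = 250, s_exc = 3000, s_inh = 3000,
                   duty = 0.5),
    oscillator = list(f_unit = 2332.7, V_f = 0.3504, gate_floor = 0.005,
                      n_stages = 3L),
    soma = list(C_mem = 10, g_leak = 1, V_rest = -70, V_thresh = -45,
                V_reset = -70, t_refr = 3e-3),
    dendrite = list(C_den = 8.5, R_c = 100, E_leak = -60),
    network = list(configuration = "single_compartment",
                   V_post_clamp = -70),
    learning = list(t_pre = 0.015, schedule = "linear", t_post0 = 0.005,
                    t_post_max = 0.040, t_ramp = 150, w0 = 8L),
    experiment = list(dt = 1e-4, window = 75, n_runs = 50L),
    seed = 1L
  )
}

#' Load a run configuration
#'
#' Reads a YAML configuration file, validates it against the known
#' blocks/keys (unknown keys are rejected), and fills every missing key
#' with the package default so the returned object is fully materialized.
#' A stable hash of the effective configuration is attached for
#' provenance.
#'
#' @param path YAML file path, or `NULL` for the pure defaults.
#' @return A named list of configuration blocks with attribute
#'   `config_hash`.
#' @export
load_config <- function(path = NULL) {
  defaults <- .default_config()
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (!is.list(user)) stop("load_config: top level must be a mapping")

  unknown_block <- setdiff(names(user), names(defaults))
  if (length(unknown_block) > 0) {
    stop("load_config: unknown configuration block '", unknown_block[1], "'")
  }
  out <- defaults
  for (blk in names(user)) {
    if (!is.list(defaults[[blk]])) {
      out[[blk]] <- user[[blk]]
      next
    }
    unknown <- setdiff(names(user[[blk]]), names(defaults[[blk]]))
    if (length(unknown) > 0) {
      stop("load_config: unknown key '", blk, "$", unknown[1], "'")
    }
    out[[blk]][names(user[[blk]])] <- user[[blk]]
  }
  rf <- out$task$repeat_fraction
  if (rf < 0 || rf > 0.5) {
    stop("load_config: task$repeat_fraction must lie in [0, 0.5]")
  }
  attr(out, "config_hash") <- rlang::hash(out)
  out
}

#' Save an effective configuration
#'
#' Writes the fully materialized configuration back to YAML (for
#' provenance next to run outputs).
#'
#' @param cfg A configuration list from [load_config()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
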