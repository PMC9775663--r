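# Small builders shared across test files.

# inverter with the worked constants used in several closed-form checks
ref_inverter <- function() {
  inverter_params(I0_n = 1e-12, I0_p = 1e-12, kappa_n = 0.7, kappa_p = 0.7,
                  C_out = 5e-15, U_T = 0.0258)
}

# a miniature task for fast generator tests
small_task <- function(...) {
  args <- utils::modifyList(
    list(n_aff = 16L, duration = 5, repeat_fraction = 0.25), list(...))
  do.call(task_config, args)
}

# brute-force STDP oracle: replays the full event stream, scanning the
# history for the most recent pre/post spike at every event, independent of
# the incremental state machine in the package.
stdp_bruteforce <- function(events, n_syn, w0 = 8L, params = learning_params()) {
  ord <- order(events$time, events$type != "pre")
  events <- events[ord, , drop = FALSE]
  w <- rep(as.integer(w0), n_syn)
  for (i in seq_len(nrow(events))) {
    t_now <- events$time[i]
    past <- events[seq_len(i - 1), , drop = FALSE]
    if (events$type[i] == "post") {
      for (s in seq_len(n_syn)) {
        pres <- past$time[past$type == "pre" & past$syn == s]
        if (length(pres) == 0) next
        tj <- max(pres)
        if (tj <= t_now && (t_now - tj) < params$t_pre && w[s] < params$w_max) {
          w[s] <- w[s] + 1L
        }
      }
    } else {
      s <- events$syn[i]
      posts <- past$time[past$type == "post"]
      if (length(posts) > 0) {
        ti <- max(posts)
        tp <- t_post_at(t_now, params)
        if (t_now > ti && (t_now - ti) < tp && w[s] > params$w_min) {
          w[s] <- w[s] - 1L
        }
      }
    }
  }
  w
}

# random pre/post event stream
random_events <- function(n_events, n_syn, t_max = 1, p_post = 0.3) {
  tibble::tibble(
    time = sort(stats::runif(n_events, 0, t_max)),
    type = ifelse(stats::runif(n_events) < p_post, "post", "pre"),
    syn = sample.int(n_syn, n_events, replace = TRUE)
  )
}
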