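test_that("rate profiles respect the bounds and the slew limit", {
  cfg <- small_task()
  set.seed(1)
  r <- gen_rate_profiles(cfg)
  expect_true(all(r >= cfg$rate_min & r <= cfg$rate_max))
  slews <- abs(diff(r)) / cfg$rate_dt
  expect_lte(max(slews), cfg$slew_max + 1e-9)
})

test_that("rate walk mean sits near mid-range; the floor lifts it moderately", {
  cfg <- task_config(n_aff = 64L, duration = 60)
  set.seed(2)
  r <- gen_rate_profiles(cfg)
  expect_equal(mean(r), 45, tolerance = 0.1)
  tr <- gen_poisson_spikes(r, cfg)
  raw_rate <- mean(lengths(tr)) / cfg$duration
  tr2 <- enforce_min_activity(tr, cfg)
  floored_rate <- mean(lengths(tr2)) / cfg$duration
  expect_gt(floored_rate, raw_rate)
  # the empty-window floor adds roughly 20 * E[exp(-r/20)] ~ 4-5 Hz
  expect_equal(floored_rate - raw_rate, 4.5, tolerance = 0.35)
})

test_that("thinned spikes follow the inhomogeneous Poisson law", {
  cfg <- task_config(n_aff = 1L, duration = 100, rate_min = 50,
                     rate_max = 50.0001)
  set.seed(3)
  r <- gen_rate_profiles(cfg)
  tr <- gen_poisson_spikes(r, cfg)[[1]]
  # count within 3 sd of 5000
  expect_lt(abs(length(tr) - 5000), 3 * sqrt(5000))
  # inter-spike intervals are exponential
  isi <- diff(tr)
  ks <- suppressWarnings(stats::ks.test(isi, "pexp", rate = 50))
  expect_gt(ks$p.value, 0.01)
  # zero rate gives an empty train
  cfg0 <- task_config(n_aff = 1L, duration = 5, rate_min = 0, rate_max = 1e-9)
  expect_length(gen_poisson_spikes(gen_rate_profiles(cfg0), cfg0)[[1]], 0)
})

test_that("the minimum-activity floor guarantees a spike in every window", {
  cfg <- small_task()
  # an already dense train is untouched
  dense <- list(seq(0.001, cfg$duration - 0.001, by = 0.01))
  expect_identical(enforce_min_activity(dense, cfg)[[1]], dense[[1]])
  # an empty train receives exactly one spike per 50 ms window
  set.seed(4)
  empty <- enforce_min_activity(list(numeric(0)), cfg)[[1]]
  expect_length(empty, cfg$duration / 0.05)
  expect_true(all(table(floor(empty / 0.05)) == 1))
  # generic post-condition over a random train
  tr <- gen_poisson_spikes(gen_rate_profiles(cfg), cfg)
  tr <- enforce_min_activity(tr, cfg)
  for (tt in tr) {
    expect_length(unique(floor(tt / 0.05)), cfg$duration / 0.05)
  }
})

test_that("pattern embedding places the right number of non-adjacent copies", {
  cfg <- small_task(duration = 30)  # 600 sections -> 150 occurrences
  set.seed(5)
  tr <- enforce_min_activity(
    gen_poisson_spikes(gen_rate_profiles(cfg), cfg), cfg)
  ts <- embed_pattern(tr, cfg)
  n_expect <- round(cfg$repeat_fraction * cfg$n_sections)
  expect_length(ts$occurrences, n_expect)
  secs <- round(ts$occurrences / cfg$section)
  expect_true(all(diff(sort(secs)) >= 2))
  expect_true(all(ts$occurrences %% cfg$section < 1e-9 |
                    cfg$section - ts$occurrences %% cfg$section < 1e-9))

  # every occurrence carries exactly the pattern, afferent by afferent
  lst <- split(ts$spikes$time, ts$spikes$afferent)
  pat <- split(ts$pattern$offset, factor(ts$pattern$afferent, 1:cfg$n_aff))
  for (a in seq_len(cfg$n_aff)) {
    for (s in ts$occurrences[1:5]) {
      inside <- lst[[a]][lst[[a]] >= s & lst[[a]] < s + cfg$section] - s
      expect_equal(inside, sort(pat[[a]]), tolerance = 1e-9)
    }
  }
})

test_that("zero repeat fraction leaves the trains untouched", {
  cfg <- small_task(repeat_fraction = 0)
  set.seed(6)
  tr <- enforce_min_activity(
    gen_poisson_spikes(gen_rate_profiles(cfg), cfg), cfg)
  ts <- embed_pattern(tr, cfg)
  expect_length(ts$occurrences, 0)
  expect_identical(spike_train_list(ts), tr)
})

test_that("an over-dense repeat fraction is rejected as infeasible", {
  expect_error(task_config(repeat_fraction = 0.6), "0.5")
})

test_that("population rate statistics partition correctly", {
  # a single afferent at exactly 20 Hz, no pattern
  cfg <- task_config(n_aff = 1L, duration = 10, repeat_fraction = 0)
  ts <- new_spike_train_set(list(seq(0.025, 9.999, by = 0.05)),
                            pattern = NULL, occurrences = numeric(0),
                            cfg = cfg)
  st <- population_rate_stats(ts)
  expect_true(st$degenerate)
  expect_true(is.na(st$rate_inside))
  expect_equal(st$rate_outside, 20)
})

test_that("the spike-train set invariants hold across many seeds", {
  for (seed in 1:50) {
    cfg <- small_task()
    ts <- generate_spike_trains(cfg, seed = seed)
    sp <- split(ts$spikes$time, ts$spikes$afferent)
    expect_true(all(vapply(sp, function(x) !is.unsorted(x, strictly = TRUE),
                           logical(1))))
    expect_true(all(ts$spikes$time >= 0 & ts$spikes$time <= cfg$duration))
    secs <- round(ts$occurrences / cfg$section)
    expect_true(length(secs) == 0 || all(diff(secs) >= 2))
  }
})

test_that("the pattern is invisible in the population rate", {
  cfg <- task_config(n_aff = 64L, duration = 60)
  ts <- generate_spike_trains(cfg, seed = 11)
  st <- population_rate_stats(ts)
  expect_false(st$degenerate)
  expect_lt(abs(st$rate_inside - st$rate_outside) / st$rate_outside, 0.1)

  # two-sample test: the pattern's five 10 ms bins (its independent draws;
  # every occurrence is a copy of the same five values) against the
  # distribution of outside bins
  n_bins <- round(cfg$duration / 0.01)
  bin_id <- pmin(floor(ts$spikes$time / 0.01), n_bins - 1)
  counts <- tabulate(bin_id + 1L, nbins = n_bins)
  inside <- rep(FALSE, n_bins)
  for (s in ts$occurrences) inside[(round(s / 0.01) + 1):(round(s / 0.01) + 5)] <- TRUE
  b0 <- round(ts$occurrences[1] / 0.01)
  pattern_bins <- counts[(b0 + 1):(b0 + 5)]
  tt <- stats::t.test(pattern_bins, counts[!inside])
  expect_gt(tt$p.value, 0.01)
})
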