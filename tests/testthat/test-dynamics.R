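# Seizures with exact onsets and controlled perturbation scales: the seizure
# start is exactly the requested onset (so window membership is deterministic)
# while the spike times and the seizure end carry the timing noise.
make_noisy_seizures <- function(onsets, sigmas, n_spikes = 12, base_int = 0.4) {
  offsets <- seq(0.5, by = base_int, length.out = n_spikes)
  Map(function(o, s) {
    times <- o + sort(offsets + rnorm(n_spikes, sd = s))
    seizure("ch1", o, max(times) + 0.5, spike_train(times, refractory_s = 0))
  }, onsets, sigmas)
}

test_that("windowed_jitter averages exactly the in-window seizure pairs", {
  set.seed(61)
  szs <- make_noisy_seizures(c(0, 40, 80, 150, 190), rep(0.01, 5))
  trace <- windowed_jitter(szs, window_s = 100, step_s = 50)
  m <- pairwise_jitter(szs)
  expect_s3_class(trace, "jitter_trace")
  expect_equal(trace$window_start_s, c(0, 50, 100))
  # window [0, 100): seizures 1-3; [50, 150): 3 only; [100, 200): 4-5
  expect_equal(trace$n_seizures_in_window, c(3L, 1L, 2L))
  expect_equal(trace$jitter_pct[1], mean(c(m[1, 2], m[1, 3], m[2, 3])))
  expect_true(is.na(trace$jitter_pct[2]))
  expect_equal(trace$jitter_pct[3], m[4, 5])
  expect_equal(attr(trace, "window_s"), 100)
  expect_error(windowed_jitter(rev(szs)), "time-ordered")
  expect_error(windowed_jitter(szs, window_s = -1), "positive")
})

test_that("event_windowed_jitter slides one seizure at a time", {
  set.seed(62)
  szs <- make_noisy_seizures(c(0, 30, 60, 90), rep(0.01, 4))
  trace <- event_windowed_jitter(szs, events_per_window = 2)
  expect_equal(nrow(trace), 3)
  expect_equal(trace$window_start_s, seizure_onsets(szs)[1:3])
  expected <- vapply(1:3, function(k) {
    jitter(szs[[k]], szs[[k + 1]])$jitter_pct
  }, numeric(1))
  expect_equal(trace$jitter_pct, expected)
  expect_error(event_windowed_jitter(szs, 1), "at least 2")
  expect_error(event_windowed_jitter(szs[1], 2), "fewer seizures")
})

test_that("bin_trace reproduces quantile summaries per bin", {
  trace <- make_trace(seq(0, 550, by = 50),
                      c(1, 2, 3, 4, 5, 6, NA, 10, 20, 30, 40, 50))
  b <- bin_trace(trace, bin_s = 300)
  expect_equal(nrow(b), 2)
  expect_equal(b$bin_start_s, c(0, 300))
  expect_equal(b$n, c(6L, 5L))
  expect_equal(b$median[1], median(1:6))
  expect_equal(b$q25[2], unname(quantile(c(10, 20, 30, 40, 50), 0.25)))
  expect_equal(b$max[2], 50)
  expect_error(bin_trace(trace[0, ]), "empty trace")
})

test_that("detect_transitions thresholds at mean + k.SD with excess-weighted timing", {
  v <- c(2, 2, 2, 2, 2, 9, 12, 2, 2, 2, 2, 2)
  trace <- make_trace(seq(0, by = 600, length.out = length(v)), v,
                      window_s = 3600, step_s = 600)
  tr <- detect_transitions(trace, k_sd = 1)
  mu <- mean(v); sdv <- sd(v); thr <- mu + 1 * sdv
  expect_equal(attr(tr, "threshold"), thr)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$onset_s, 3000)
  expect_equal(tr$offset_s, 3600 + 3600)
  expect_equal(tr$peak_jitter_pct, 12)
  centers <- c(3000, 3600) + 1800
  excess <- c(9, 12) - thr
  expect_equal(tr$change_time_s, sum(excess * centers) / sum(excess))
})

test_that("constant traces and missing points are handled in transition calling", {
  flat <- make_trace(seq(0, by = 600, length.out = 8), rep(3, 8))
  expect_equal(nrow(detect_transitions(flat)), 0)
  # an NA splits one super-threshold stretch into two transitions
  v <- c(1, 1, 1, 1, 8, NA, 8, 1, 1, 1, 1, 1)
  broken <- make_trace(seq(0, by = 600, length.out = length(v)), v)
  tr <- detect_transitions(broken, k_sd = 1)
  expect_equal(nrow(tr), 2)
  expect_error(detect_transitions(make_trace(c(0, 600), c(NA, NA))),
               "trace points missing")
  expect_error(detect_transitions(make_trace(c(0, 600), c(1, 2))),
               "at least 3")
})

test_that("cross-state pairs are larger and counted correctly around a transition", {
  set.seed(63)
  base_a <- sort(runif(10, 0, 8))
  base_b <- sort(runif(10, 0, 8))
  mk <- function(onset, base) make_seizure(onset +
                                             sort(base + rnorm(10, sd = 0.002)))
  szs <- c(lapply(c(0, 30, 60), mk, base = base_a),
           lapply(c(200, 230, 260), mk, base = base_b))
  transitions <- data.frame(onset_s = 100, offset_s = 160,
                            peak_jitter_pct = 50, change_time_s = 130)
  res <- state_vs_transition_jitter(szs, transitions)
  expect_length(res$within, 6)   # C(3,2) per segment, two segments
  expect_length(res$cross, 9)    # 3 x 3 across the transition
  expect_gt(min(res$cross), max(res$within))
  capped <- state_vs_transition_jitter(szs, transitions, max_per_side = 1)
  expect_length(capped$cross, 1)
  expect_equal(capped$cross, jitter(szs[[3]], szs[[4]])$jitter_pct)
  # a seizure inside the transition interval joins neither sample
  szs_mid <- append(szs, list(mk(120, base_a)), after = 3)
  res_mid <- state_vs_transition_jitter(szs_mid, transitions)
  expect_length(res_mid$within, 6)
  expect_length(res_mid$cross, 9)
})

test_that("fano matches variance over mean and validates input", {
  expect_equal(fano(rep(7, 10)), 0)
  expect_equal(fano(c(1, 3)), var(c(1, 3)) / 2)
  x <- rgamma(50, shape = 3, rate = 0.1)
  expect_equal(fano(x), var(x) / mean(x))
  expect_error(fano(5), "at least 2")
  expect_error(fano(c(-2, 0, 2)), "mean must be positive")
})

test_that("windowed jitter correlates with seizure-timing variability", {
  set.seed(64)
  # three window groups: spike-timing noise, duration spread, and onset
  # interval spread all increase from group to group
  onsets <- c(0, 30.1, 60, 200, 228, 262, 400, 425, 465)
  sigmas <- rep(c(0.002, 0.02, 0.08), each = 3)
  szs <- make_noisy_seizures(onsets, sigmas)
  trace <- windowed_jitter(szs, window_s = 100, step_s = 200)
  res <- jitter_variability_correlation(trace, szs, stat = "duration_sd")
  expect_equal(res$n, 3)
  expect_gt(res$r, 0.5)
  res_i <- jitter_variability_correlation(trace, szs, stat = "interval_sd")
  expect_equal(res_i$n, 3)
  expect_gt(res_i$r, 0.5)
  ev <- event_windowed_jitter(szs)
  expect_error(jitter_variability_correlation(ev, szs), "time window")
})
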