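test_that("estimate_background matches the noise scale and honors exclusions", {
  set.seed(41)
  rate <- 2000
  x <- rnorm(60 * rate, sd = 25e-6)
  rec <- recording(x, rate)
  expect_equal(estimate_background(rec), 25e-6, tolerance = 0.05)

  # a large artifact inflates the raw estimate; excluding it restores it
  rec2 <- rec
  t <- time_axis(rec2)
  rec2$samples[1, t >= 10 & t < 30] <- 2e-3
  excl <- event_table("ch1", 10, 30, "seizure")
  expect_gt(estimate_background(rec2), 2 * 25e-6)
  expect_equal(estimate_background(rec2, exclusion = excl), 25e-6,
               tolerance = 0.05)
  short <- recording(rnorm(rate / 2, sd = 1e-6), rate)
  expect_error(estimate_background(short), "less than 1 s")
})

test_that("detect_params validates thresholds and flags unusual offsets", {
  expect_error(detect_params(upper_v = 1e-3, lower_v = 2e-3), "below upper_v")
  expect_error(detect_params(min_excursion_s = 0.2, max_excursion_s = 0.1),
               "below max_excursion_s")
  expect_warning(detect_params(seizure_offset_v = 10e-6), "20-65")
  expect_warning(detect_params(seizure_offset_v = 80e-6), "20-65")
  expect_silent(detect_params(seizure_offset_v = 40e-6))
})

test_that("detect_spikes recovers pulse times, amplitudes, and rejects by the dual threshold", {
  set.seed(42)
  rate <- 6000
  times <- seq(1, 15, by = 0.4)
  rec <- make_burst_recording(times, duration_s = 16, rate_hz = rate)
  train <- detect_spikes(rec)
  expect_length(train$times_s, length(times))
  expect_lt(max(abs(train$times_s - times)), 1e-3)
  expect_equal(unname(train$peak_amp_v), rep(1.2e-3, length(times)),
               tolerance = 0.1)

  # a pulse peaking between the two thresholds is not a spike
  low <- make_burst_recording(5, duration_s = 10, amp_v = 0.8e-3,
                              noise_sd_v = 0)
  expect_length(detect_spikes(low)$times_s, 0)
  # an excursion wider than max_excursion_s is rejected
  wide <- make_burst_recording(5, duration_s = 10, width_s = 0.3,
                               noise_sd_v = 0)
  expect_length(detect_spikes(wide)$times_s, 0)
  # and one narrower than min_excursion_s as well
  narrow <- make_burst_recording(5, duration_s = 10, width_s = 0.004,
                                 noise_sd_v = 0)
  expect_length(detect_spikes(narrow)$times_s, 0)
})

test_that("biphasic peaks within the refractory period merge to the larger peak", {
  rate <- 6000
  x <- numeric(10 * rate)
  add_pulse <- function(x, t, amp) {
    n <- round(0.01 * rate)
    idx <- round(t * rate) + seq_len(n) - round(n / 2)
    x[idx] <- x[idx] + amp * sin(pi * seq_len(n) / (n + 1))
    x
  }
  x <- add_pulse(x, 2.00, 1.5e-3)
  x <- add_pulse(x, 2.05, 1.2e-3)   # within 100 ms of the first -> merged
  x <- add_pulse(x, 5.00, 1.2e-3)
  x <- add_pulse(x, 5.05, 1.2e-3)   # exact tie -> earlier peak kept
  x <- add_pulse(x, 8.00, 1.2e-3)
  x <- add_pulse(x, 8.20, 1.3e-3)   # outside the refractory -> two spikes
  train <- detect_spikes(recording(x, rate))
  expect_equal(train$times_s, c(2.00, 5.00, 8.00, 8.20), tolerance = 1e-3)
  expect_equal(unname(train$peak_amp_v[1]), 1.5e-3, tolerance = 1e-2)
})

test_that("detect_seizures finds one seizure with tight bounds and attached spikes", {
  set.seed(43)
  times <- seq(20, 40, by = 0.5)  # 41 pulses, 2 Hz, 20 s
  rec <- make_burst_recording(times, duration_s = 60)
  szs <- detect_seizures(rec)
  expect_length(szs, 1)
  sz <- szs[[1]]
  tol <- 0.5 + detect_params()$gap_tol_s
  expect_lt(abs(sz$start_s - 20), tol)
  expect_lt(abs(sz$end_s - 40), tol)
  expect_length(sz$spikes$times_s, length(times))
  expect_lt(max(abs(sz$spikes$times_s - times)), 1e-3)
  expect_gte(sz$mean_event_rate_hz, 2)
})

test_that("too-short and too-sparse candidates are rejected; gaps bridge only within tolerance", {
  set.seed(44)
  # 8 s of 2 Hz activity: shorter than the 10 s minimum
  short <- make_burst_recording(seq(10, 18, by = 0.5), duration_s = 30)
  expect_length(detect_seizures(short), 0)
  # 30 s of 1 Hz activity: below the 2 Hz minimum rate
  sparse <- make_burst_recording(seq(10, 40, by = 1), duration_s = 60)
  expect_length(detect_seizures(sparse), 0)
  # two 8 s halves split by a 1.5 s gap bridge into one 17.5 s seizure ...
  bridged_times <- c(seq(10, 18, by = 0.4), seq(19.5, 27.5, by = 0.4))
  bridged <- make_burst_recording(bridged_times, duration_s = 40)
  szs <- detect_seizures(bridged)
  expect_length(szs, 1)
  expect_gt(szs[[1]]$end_s - szs[[1]]$start_s, 15)
  # ... but a 3 s gap leaves two sub-minimum halves and no seizure
  split_times <- c(seq(10, 18, by = 0.4), seq(21, 29, by = 0.4))
  split <- make_burst_recording(split_times, duration_s = 40)
  expect_length(detect_seizures(split), 0)
})

test_that("an explicit seizure threshold overrides the background estimate", {
  set.seed(45)
  rec <- make_burst_recording(seq(10, 30, by = 0.45), duration_s = 45)
  expect_length(detect_seizures(rec), 1)
  high <- detect_params(seizure_thresh_v = 5e-3)
  expect_length(detect_seizures(rec, high), 0)
})

test_that("raster_counts counts super-threshold bins per sliding window", {
  rate <- 1000
  x <- numeric(30 * rate)
  # super-threshold half-sine pulses centred in chosen 0.5 s bins
  pulse_bins <- c(1, 2, 5, 24)
  for (b in pulse_bins) {
    n <- round(0.01 * rate)
    i0 <- round((b - 0.75) * 0.5 * rate)
    x[i0 + seq_len(n)] <- 1e-3 * sin(pi * seq_len(n) / (n + 1))
  }
  params <- detect_params(seizure_thresh_v = 1e-4)
  rc <- raster_counts(recording(x, rate), params)
  expect_equal(rc$window_start_s[1], 0)
  expect_equal(diff(rc$window_start_s)[1], 0.5, tolerance = 1e-12)
  # window k covers bins k..k+19; reproduce the counts independently
  super <- seq_len(60) %in% pulse_bins
  expected <- vapply(seq_len(60 - 20 + 1), function(k) sum(super[k:(k + 19)]),
                     numeric(1))
  expect_equal(rc$count, as.integer(expected))
  expect_error(raster_counts(recording(numeric(5 * rate), rate), params),
               "shorter than the raster window")
})

test_that("spike overrides add and remove spikes by time", {
  train <- spike_train(c(1, 2, 3), c(1e-3, 1.1e-3, 1.2e-3), refractory_s = 0)
  ov <- event_table(channel_id = c("ch1", "ch1"),
                    start_s = c(2.004, 5), end_s = c(2.004, 5),
                    kind = c("spike", "spike"), value = c(-1, 1.3e-3))
  fixed <- apply_spike_overrides(train, ov)
  expect_equal(fixed$times_s, c(1, 3, 5))
  expect_equal(unname(fixed$peak_amp_v[3]), 1.3e-3)
  # removal misses when no detected spike lies within the tolerance
  far <- event_table("ch1", 2.5, 2.5, "spike", value = -1)
  expect_equal(apply_spike_overrides(train, far)$times_s, c(1, 2, 3))
})
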