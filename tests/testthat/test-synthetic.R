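test_that("seizure templates realize the two canonical shapes exactly", {
  ab <- seizure_template("abrupt_onset", duration_s = 20, mean_rate_hz = 3)
  expect_equal(ab$spike_offsets_s[1], 0)
  expect_equal(max(ab$spike_offsets_s), 20, tolerance = 1e-9)
  expect_length(ab$spike_offsets_s, 60)
  ints <- diff(ab$spike_offsets_s)
  expect_true(all(diff(ints) > 0))  # intervals lengthen toward termination
  expect_equal(ab$spike_amps_v[1], 1.5 * 1.2e-3)
  expect_true(all(ab$spike_amps_v[-1] == 1.2e-3))

  rp <- seizure_template("ramping", duration_s = 16, mean_rate_hz = 2.5)
  ri <- diff(rp$spike_offsets_s)
  k <- which.min(ri)
  expect_true(all(diff(ri[1:k]) <= 0))        # rate ramps up ...
  expect_true(all(diff(ri[k:length(ri)]) >= 0))  # ... then fades out
  expect_equal(max(rp$spike_offsets_s), 16, tolerance = 1e-9)

  expect_error(seizure_template(duration_s = 5), ">= 10 s")
  expect_error(seizure_template(mean_rate_hz = 1), ">= 2 Hz")
  expect_error(seizure_template(interval_spread = 0.9), "interval_spread")
})

test_that("render_seizure adds timing noise but preserves the template skeleton", {
  tmpl <- seizure_template("abrupt_onset")
  set.seed(51)
  noiseless <- render_seizure(tmpl, timing_noise_sd_s = 0)
  expect_equal(noiseless$times_s, tmpl$spike_offsets_s, tolerance = 1e-12)
  noisy <- render_seizure(tmpl, timing_noise_sd_s = 0.005)
  expect_length(noisy$times_s, length(tmpl$spike_offsets_s))
  expect_true(all(diff(noisy$times_s) > 0.1))  # refractory respected
  dev <- noisy$times_s - tmpl$spike_offsets_s
  expect_lt(max(abs(dev)), 0.03)  # perturbations stay on the 5 ms scale
  expect_error(render_seizure(tmpl, timing_noise_sd_s = 10), "timing noise")
})

test_that("simulation is deterministic in the seed and leaves the RNG untouched", {
  cfg <- sim_config(duration_s = 40, rate_hz = 2000,
                    seizure_times_s = 10, seed = 7)
  set.seed(99)
  before <- .Random.seed
  sim1 <- simulate_recording(cfg)
  expect_identical(.Random.seed, before)  # global RNG state restored
  sim2 <- simulate_recording(cfg)
  expect_identical(sim1$recording$samples, sim2$recording$samples)
  expect_identical(as.data.frame(sim1$truth), as.data.frame(sim2$truth))
  cfg2 <- sim_config(duration_s = 40, rate_hz = 2000,
                     seizure_times_s = 10, seed = 8)
  expect_false(identical(simulate_recording(cfg2)$recording$samples,
                         sim1$recording$samples))
})

test_that("sim_config validates schedules and placements", {
  tm <- list(seizure_template("abrupt_onset"), seizure_template("ramping"))
  expect_error(sim_config(100, templates = tm,
                          state_schedule = data.frame(switch_time_s = c(50, 40),
                                                      template_index = c(2, 1))),
               "strictly increasing")
  expect_error(sim_config(100, templates = tm,
                          state_schedule = data.frame(switch_time_s = 150,
                                                      template_index = 2)),
               "beyond the recording")
  expect_error(sim_config(100, templates = tm,
                          state_schedule = data.frame(switch_time_s = 50,
                                                      template_index = 3)),
               "unknown template")
  expect_error(simulate_seizure_sequence(
    sim_config(100, seizure_times_s = c(10, 20))), "overlap")
  expect_error(simulate_seizure_sequence(
    sim_config(100, seizure_times_s = 90)), "beyond the recording")
})

test_that("the ground-truth table matches the rendered seizures", {
  cfg <- sim_config(duration_s = 120, rate_hz = 1000,
                    seizure_times_s = c(10, 60), seed = 3)
  sim <- simulate_recording(cfg)
  expect_equal(n_samples(sim$recording), 120 * 1000)
  sz_rows <- sim$truth[sim$truth$kind == "seizure", ]
  spike_rows <- sim$truth[sim$truth$kind == "spike", ]
  expect_equal(nrow(sz_rows), 2)
  expect_equal(nrow(spike_rows), 2 * 60)
  expect_equal(sort(vapply(sim$seizures, `[[`, numeric(1), "start_s")),
               sort(sz_rows$start_s))
  # every truth spike lies inside a truth seizure
  inside <- vapply(spike_rows$start_s, function(ts) {
    any(ts >= sz_rows$start_s - 1e-9 & ts <= sz_rows$end_s + 1e-9)
  }, logical(1))
  expect_true(all(inside))
})

test_that("scheduled state switches change the rendering template", {
  tm <- list(seizure_template("abrupt_onset"),
             seizure_template("ramping", mean_rate_hz = 2.5))
  cfg <- sim_config(duration_s = 400, templates = tm,
                    state_schedule = data.frame(switch_time_s = 200,
                                                template_index = 2),
                    seizure_times_s = c(50, 120, 250, 320), seed = 4)
  seq_out <- simulate_seizure_sequence(cfg)
  expect_equal(seq_out$template_index, c(1L, 1L, 2L, 2L))
  expect_equal(seq_out$transition_times_s, 200)
  n_spikes <- vapply(seq_out$seizures,
                     function(s) length(s$spikes$times_s), integer(1))
  expect_equal(n_spikes, c(60L, 60L, 50L, 50L))
})

test_that("detected jitter from a full simulation matches an interval-level Monte-Carlo oracle", {
  cfg <- sim_config(duration_s = 230, seizure_times_s = seq(10, 190, by = 45),
                    seed = 5)
  sim <- simulate_recording(cfg)
  szs <- detect_seizures(sim$recording)
  expect_length(szs, 5)
  m <- pairwise_jitter(szs)
  obs <- mean(m[upper.tri(m)])
  set.seed(52)
  oracle <- mc_expected_jitter(seizure_template("abrupt_onset")$spike_offsets_s,
                               sigma = 0.005, n_sim = 500)
  expect_lt(abs(obs - oracle) / oracle, 0.15)
})

test_that("simulated calcium traces honor their programmed ground truth", {
  sim <- simulate_calcium(duration_s = 2400, seed = 6)
  expect_equal(sim$truth$recovery_s, 900)
  t <- sim$affected$t_s
  # the transient peaks near event + rise time on the affected trace only
  base <- 100 + 5 * t / 3600
  aff_dff <- sim$affected$f / base - 1
  ref_dff <- sim$reference$f / base - 1
  win <- t >= 75 & t <= 85
  expect_gt(mean(aff_dff[win]), 0.4)
  expect_lt(mean(abs(ref_dff[win])), 0.1)
  # after the programmed recovery both traces sit near their shared baseline
  late <- t >= 60 + 900 & t <= 60 + 900 + 120
  expect_lt(mean(abs(aff_dff[late] - ref_dff[late])), 0.02)
  expect_error(simulate_calcium(recovery_s = 10, rise_s = 20),
               "must exceed rise_s")
})
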