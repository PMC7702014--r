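# Independent oracles and fixture builders used across the suite.

# Naive jitter re-implementation: pairs intervals by their signed offset from
# the alignment spikes via explicit offset bookkeeping, independent of the
# shift-based implementation in the package.
naive_jitter_at <- function(ta, tb, ia, ib) {
  int_a <- diff(ta)
  int_b <- diff(tb)
  offs_a <- seq_along(int_a) - ia
  offs_b <- seq_along(int_b) - ib
  common <- intersect(offs_a, offs_b)
  if (!length(common)) return(NULL)
  va <- int_a[match(common, offs_a)]
  vb <- int_b[match(common, offs_b)]
  list(jitter_pct = 100 * mean(abs(va - vb) / ((va + vb) / 2)),
       n_interval = length(common))
}

# Brute-force minimum over the full alignment grid.
naive_min_jitter <- function(ta, tb) {
  best <- Inf
  for (ia in seq_along(ta)) {
    for (ib in seq_along(tb)) {
      res <- naive_jitter_at(ta, tb, ia, ib)
      if (!is.null(res) && res$jitter_pct < best) best <- res$jitter_pct
    }
  }
  best
}

# Monte-Carlo expectation of the true-alignment jitter between two renderings
# of one spike-offset template under iid Gaussian timing noise. Operates on
# intervals directly; no waveform, detection, or alignment search involved.
mc_expected_jitter <- function(offsets, sigma, n_sim = 2000) {
  vals <- vapply(seq_len(n_sim), function(i) {
    ta <- sort(offsets + rnorm(length(offsets), sd = sigma))
    tb <- sort(offsets + rnorm(length(offsets), sd = sigma))
    ia <- diff(ta)
    ib <- diff(tb)
    100 * mean(abs(ia - ib) / ((ia + ib) / 2))
  }, numeric(1))
  mean(vals)
}

# Random spike train with intervals in [0.15, 0.5] s.
random_train <- function(n) {
  spike_train(cumsum(c(runif(1, 0, 5), runif(n - 1, 0.15, 0.5))),
              refractory_s = 0)
}

# Recording holding sharp half-sine test pulses (10 ms wide, default 1.2 mV)
# at the given peak times over Gaussian noise. Independent of the package's
# biphasic kernel.
make_burst_recording <- function(pulse_times_s, duration_s, rate_hz = 6000,
                                 amp_v = 1.2e-3, noise_sd_v = 20e-6,
                                 width_s = 0.010) {
  n <- round(duration_s * rate_hz)
  x <- rnorm(n, sd = noise_sd_v)
  half_n <- round(width_s * rate_hz)
  pulse <- amp_v * sin(pi * seq_len(half_n) / (half_n + 1))
  for (tp in pulse_times_s) {
    i0 <- round(tp * rate_hz) + 1 - round(half_n / 2)
    idx <- seq(i0, length.out = half_n)
    ok <- idx >= 1 & idx <= n
    x[idx[ok]] <- x[idx[ok]] + pulse[ok]
  }
  recording(x, rate_hz = rate_hz)
}

# Seizure object from explicit absolute spike times.
make_seizure <- function(times_s, channel = "ch1", pad_s = 0.05) {
  seizure(channel, min(times_s) - pad_s, max(times_s) + pad_s,
          spike_train(times_s, refractory_s = 0))
}

# Manual jitter_trace constructor for tests.
make_trace <- function(window_start_s, jitter_pct,
                       n_seizures = rep(2L, length(jitter_pct)),
                       window_s = 3600, step_s = 600) {
  out <- data.frame(window_start_s = window_start_s, jitter_pct = jitter_pct,
                    n_seizures_in_window = as.integer(n_seizures))
  attr(out, "window_s") <- window_s
  attr(out, "step_s") <- step_s
  class(out) <- c("jitter_trace", "data.frame")
  out
}
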