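# Synthetic ground-truth generators: parameterized epileptiform seizure
# templates, per-spike Gaussian timing noise, scheduled waveform-state
# switches, background noise, and fluorescence traces with a programmed
# insertion transient. All generators are pure functions of (config, seed).

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Seizure waveform template
#'
#' A template is a deterministic sequence of spike time offsets (starting at
#' 0) with per-spike amplitudes, emulating the two canonical seizure shapes:
#' * `abrupt_onset`: begins with the largest-amplitude spike and high-rate
#'   spiking whose inter-spike intervals lengthen monotonically toward
#'   termination.
#' * `ramping`: the spike rate ramps up, peaks mid-event, and fades out
#'   (intervals decrease, then increase).
#'
#' @param kind `"abrupt_onset"` or `"ramping"`.
#' @param duration_s total template duration (>= 10 s; default 20).
#' @param mean_rate_hz mean spike rate (>= 2 Hz; default 3).
#' @param spike_amp_v base spike amplitude, volts (default 1.2 mV).
#' @param first_amp_factor amplitude multiplier of the leading spike for
#'   `abrupt_onset` (default 1.5).
#' @param interval_spread fractional spread of the interval ramp around the
#'   mean interval, in `(0, 0.7)` (default 0.45).
#' @return object of class `seizure_template` with `kind`, `spike_offsets_s`,
#'   `spike_amps_v`.
#' @export
seizure_template <- function(kind = c("abrupt_onset", "ramping"),
                             duration_s = 20, mean_rate_hz = 3,
                             spike_amp_v = 1.2e-3, first_amp_factor = 1.5,
                             interval_spread = 0.45) {
  kind <- match.arg(kind)
  if (duration_s < 10) stop("template duration must be >= 10 s", call. = FALSE)
  if (mean_rate_hz < 2) stop("template mean rate must be >= 2 Hz", call. = FALSE)
  if (interval_spread <= 0 || interval_spread >= 0.7) {
    stop("interval_spread must be in (0, 0.7)", call. = FALSE)
  }
  n <- max(3L, round(duration_s * mean_rate_hz))
  n_int <- n - 1L
  shape <- switch(kind,
    abrupt_onset = seq(1 - interval_spread, 1 + interval_spread,
                       length.out = n_int),
    ramping = {
      half <- seq(1 + interval_spread, 1 - interval_spread,
                  length.out = ceiling(n_int / 2))
      c(half, rev(half))[seq_len(n_int)]
    })
  intervals <- shape * duration_s / sum(shape)
  offsets <- c(0, cumsum(intervals))
  amps <- rep(spike_amp_v, n)
  if (kind == "abrupt_onset") amps[1] <- spike_amp_v * first_amp_factor
  structure(list(kind = kind, spike_offsets_s = offsets, spike_amps_v = amps,
                 duration_s = duration_s, mean_rate_hz = mean_rate_hz),
            class = "seizure_template")
}

#' Biphasic population-spike kernel
#'
#' One positive half-sine lobe followed by a smaller opposite lobe; the
#' two-lobed shape exercises the biphasic-merge rule of the spike detector.
#' The kernel peak (where the spike time is defined) sits at 30% of the
#' width.
#'
#' @param width_s total kernel width in seconds (default 20 ms).
#' @param lobe2_frac amplitude of the second lobe relative to the first
#'   (default 0.5).
#' @return object of class `spike_kernel`.
#' @export
biphasic_kernel <- function(width_s = 0.02, lobe2_frac = 0.5) {
  structure(list(width_s = width_s, lobe2_frac = lobe2_frac),
            class = "spike_kernel")
}

# Sample the kernel at rate_hz; returns the waveform (unit peak) and the
# index of its peak.
.sample_kernel <- function(kernel, rate_hz) {
  n <- max(4L, round(kernel$width_s * rate_hz))
  split_i <- round(0.6 * n)
  t1 <- seq_len(split_i) / split_i
  t2 <- seq_len(n - split_i) / (n - split_i)
  # cubed first lobe: fast, sharply peaked spike component over a slower
  # opposite lobe, as in real population spikes
  wave <- c(sin(pi * t1)^3, -kernel$lobe2_frac * sin(pi * t2))
  list(wave = wave, peak_i = which.max(wave))
}

#' Render one seizure from a template with timing noise
#'
#' Spike times are the template offsets plus iid Gaussian perturbations,
#' re-sorted; draws violating the minimum spike separation are rejected and
#' redrawn (up to 1000 attempts). Uses the current RNG state (seed at the
#' caller, e.g. via [simulate_recording()]).
#'
#' @param template a [seizure_template()].
#' @param timing_noise_sd_s per-spike Gaussian timing noise SD (default 5 ms).
#' @param refractory_s minimum separation enforced by rejection (default
#'   0.1 s).
#' @return a [spike_train()] of relative spike times with template amplitudes.
#' @export
render_seizure <- function(template, timing_noise_sd_s = 0.005,
                           refractory_s = 0.1) {
  offsets <- template$spike_offsets_s
  amps <- template$spike_amps_v
  for (attempt in seq_len(1000)) {
    t <- offsets + stats::rnorm(length(offsets), sd = timing_noise_sd_s)
    o <- order(t)
    t <- t[o]
    if (length(t) < 2 || all(diff(t) > refractory_s)) {
      return(spike_train(t - t[1] + offsets[1], amps[o],
                         refractory_s = refractory_s))
    }
  }
  stop("timing noise too large: could not satisfy the refractory period",
       call. = FALSE)
}

#' Simulation configuration
#'
#' @param duration_s total recording duration (seconds).
#' @param rate_hz sampling rate (default 6000).
#' @param templates list of [seizure_template()] objects (default one
#'   abrupt-onset template).
#' @param state_schedule data frame with `switch_time_s` (increasing) and
#'   `template_index`: from each switch time on, seizures are rendered from
#'   the indexed template. Template 1 is active initially.
#' @param seizure_times_s explicit seizure onset times; otherwise onsets are
#'   drawn from a gamma inter-seizure-interval distribution.
#' @param isi_mean_s,isi_cv mean and coefficient of variation of the gamma
#'   inter-seizure intervals (defaults 300 s, 0.3) used when
#'   `seizure_times_s` is `NULL`.
#' @param timing_noise_sd_s per-spike timing noise SD (default 5 ms).
#' @param noise_sd_v background Gaussian noise SD in volts (default 20 uV).
#' @param kernel a [biphasic_kernel()].
#' @param seed integer RNG seed; fixed seed gives identical output.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(duration_s, rate_hz = 6000,
                       templates = list(seizure_template("abrupt_onset")),
                       state_schedule = NULL, seizure_times_s = NULL,
                       isi_mean_s = 300, isi_cv = 0.3,
                       timing_noise_sd_s = 0.005, noise_sd_v = 20e-6,
                       kernel = biphasic_kernel(), seed = 1) {
  if (inherits(templates, "seizure_template")) templates <- list(templates)
  if (!is.null(state_schedule)) {
    state_schedule <- as.data.frame(state_schedule)
    stopifnot(all(c("switch_time_s", "template_index") %in%
                    names(state_schedule)))
    if (is.unsorted(state_schedule$switch_time_s, strictly = TRUE)) {
      stop("switch times must be strictly increasing", call. = FALSE)
    }
    if (any(state_schedule$switch_time_s >= duration_s)) {
      stop("state schedule extends beyond the recording", call. = FALSE)
    }
    if (any(!state_schedule$template_index %in% seq_along(templates))) {
      stop("schedule references an unknown template", call. = FALSE)
    }
  }
  if (timing_noise_sd_s < 0) stop("timing_noise_sd_s must be >= 0", call. = FALSE)
  structure(list(duration_s = duration_s, rate_hz = rate_hz,
                 templates = templates, state_schedule = state_schedule,
                 seizure_times_s = seizure_times_s, isi_mean_s = isi_mean_s,
                 isi_cv = isi_cv, timing_noise_sd_s = timing_noise_sd_s,
                 noise_sd_v = noise_sd_v, kernel = kernel,
                 seed = as.integer(seed)),
            class = "sim_config")
}

.template_at <- function(cfg, onset) {
  idx <- 1L
  sched <- cfg$state_schedule
  if (!is.null(sched)) {
    past <- which(sched$switch_time_s <= onset)
    if (length(past)) idx <- as.integer(sched$template_index[max(past)])
  }
  idx
}

.draw_onsets <- function(cfg) {
  if (!is.null(cfg$seizure_times_s)) {
    onsets <- sort(cfg$seizure_times_s)
    dur <- vapply(onsets, function(o) {
      cfg$templates[[.template_at(cfg, o)]]$duration_s
    }, numeric(1))
    if (any(utils::head(onsets + dur, -1) > utils::tail(onsets, -1))) {
      stop("seizures overlap", call. = FALSE)
    }
    if (any(onsets < 0) || any(onsets + dur > cfg$duration_s)) {
      stop("seizure extends beyond the recording", call. = FALSE)
    }
    return(onsets)
  }
  shape <- 1 / cfg$isi_cv^2
  onsets <- numeric(0)
  t <- 0
  max_dur <- max(vapply(cfg$templates, `[[`, numeric(1), "duration_s"))
  repeat {
    gap <- stats::rgamma(1, shape = shape, rate = shape / cfg$isi_mean_s)
    gap <- max(gap, max_dur + 5)  # no overlap: gap at least the event length
    t <- t + gap
    if (t + max_dur > cfg$duration_s) break
    onsets <- c(onsets, t)
  }
  onsets
}

#' Simulate a sequence of ground-truth seizures (event level)
#'
#' Generates the seizure spike trains of a recording without rasterizing the
#' voltage waveform - the natural scale for long-duration state-transition
#' studies where only spike timing matters.
#'
#' @param cfg a [sim_config()].
#' @return list with `seizures` (ground-truth [seizure()] objects),
#'   `transition_times_s`, and `template_index` per seizure.
#' @export
simulate_seizure_sequence <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    onsets <- .draw_onsets(cfg)
    tmpl_idx <- vapply(onsets, function(o) .template_at(cfg, o), integer(1))
    seizures <- Map(function(onset, ti) {
      train <- render_seizure(cfg$templates[[ti]], cfg$timing_noise_sd_s)
      abs_train <- spike_train(onset + train$times_s, train$peak_amp_v,
                               refractory_s = 0)
      lead <- 0.3 * cfg$kernel$width_s
      seizure("ch1", min(abs_train$times_s) - lead,
              max(abs_train$times_s) + cfg$kernel$width_s - lead, abs_train)
    }, onsets, tmpl_idx)
    list(seizures = seizures,
         transition_times_s = if (is.null(cfg$state_schedule)) numeric(0)
         else cfg$state_schedule$switch_time_s,
         template_index = tmpl_idx)
  })
}

#' Simulate a full epileptiform LFP recording with ground truth
#'
#' Seizures are placed per the configuration, each rendered from the template
#' active at its onset; the voltage waveform is the sum of biphasic spike
#' kernels at the (noise-perturbed) spike times over Gaussian background
#' noise. Deterministic under a fixed seed.
#'
#' @param cfg a [sim_config()].
#' @return list with `recording` (an [recording()]), `truth` (an
#'   [event_table()] of ground-truth seizure and spike rows),
#'   `transition_times_s`, and `seizures` (ground-truth [seizure()] objects).
#' @export
simulate_recording <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  seq_out <- simulate_seizure_sequence(cfg)
  n <- round(cfg$duration_s * cfg$rate_hz)
  x <- with_seed(cfg$seed + 1L, stats::rnorm(n, sd = cfg$noise_sd_v))
  kern <- .sample_kernel(cfg$kernel, cfg$rate_hz)
  for (sz in seq_out$seizures) {
    for (k in seq_along(sz$spikes$times_s)) {
      peak_i <- round((sz$spikes$times_s[k]) * cfg$rate_hz) + 1L
      i0 <- peak_i - kern$peak_i + 1L
      idx <- seq(i0, length.out = length(kern$wave))
      ok <- idx >= 1 & idx <= n
      x[idx[ok]] <- x[idx[ok]] + sz$spikes$peak_amp_v[k] * kern$wave[ok]
    }
  }
  rec <- recording(x, rate_hz = cfg$rate_hz,
                   meta = list(source = "szjitter simulation", seed = cfg$seed))
  truth <- seizures_to_events(seq_out$seizures)
  if (length(seq_out$transition_times_s)) {
    truth <- validate_event_table(rbind(
      as.data.frame(truth),
      data.frame(channel_id = "ch1", start_s = seq_out$transition_times_s,
                 end_s = seq_out$transition_times_s, kind = "transition",
                 value = NA_real_)))
  }
  list(recording = rec, truth = truth,
       transition_times_s = seq_out$transition_times_s,
       seizures = seq_out$seizures)
}

#' Simulate fluorescence traces with a programmed insertion transient
#'
#' Produces an affected-ROI and a reference-ROI trace sharing baseline drift
#' and common-mode spontaneous calcium events; the affected trace additionally
#' carries an insertion transient that rises over `rise_s`, peaks at
#' `peak_dff`, and decays exponentially so that delta-F/F re-enters the
#' `frac` band exactly `recovery_s` seconds after the event.
#'
#' @param duration_s trace duration (default 3600 s).
#' @param rate_hz sampling rate (default 5 frames/s).
#' @param baseline_f baseline fluorescence, arbitrary units (default 100).
#' @param drift_per_hour linear baseline drift per hour, same units
#'   (default 5).
#' @param event_s electrode-insertion time (default 60 s).
#' @param peak_dff transient peak on the delta-F/F scale (default 0.5).
#' @param rise_s time to peak (default 20 s).
#' @param recovery_s programmed recovery time (default 900 s).
#' @param frac recovery band on the delta-F/F scale (default 0.02).
#' @param common_event_rate_hz rate of shared spontaneous calcium events
#'   (default 1/30 s).
#' @param common_amp_dff amplitude of shared events on the delta-F/F scale
#'   (default 0.05).
#' @param noise_sd_f additive Gaussian noise SD in fluorescence units
#'   (default 0.1; ROI-averaged gray values are smooth).
#' @param seed RNG seed.
#' @return list with `affected`, `reference` (both [fluorescence_trace()]),
#'   and `truth` (programmed `recovery_s`, `event_s`, `peak_dff`, decay
#'   `tau_s`).
#' @export
simulate_calcium <- function(duration_s = 3600, rate_hz = 5, baseline_f = 100,
                             drift_per_hour = 5, event_s = 60, peak_dff = 0.5,
                             rise_s = 20, recovery_s = 900, frac = 0.02,
                             common_event_rate_hz = 1 / 30,
                             common_amp_dff = 0.05, noise_sd_f = 0.1,
                             seed = 1) {
  if (baseline_f <= 0) stop("baseline must be positive", call. = FALSE)
  if (recovery_s <= rise_s) stop("recovery_s must exceed rise_s", call. = FALSE)
  with_seed(seed, {
    t <- seq(0, duration_s - 1 / rate_hz, by = 1 / rate_hz)
    base <- baseline_f + drift_per_hour * t / 3600
    tau <- (recovery_s - rise_s) / log(peak_dff / frac)
    te <- t - event_s
    transient <- ifelse(te < 0, 0,
                        ifelse(te <= rise_s,
                               peak_dff * 0.5 * (1 - cos(pi * te / rise_s)),
                               peak_dff * exp(-(te - rise_s) / tau)))
    common <- numeric(length(t))
    n_ev <- stats::rpois(1, common_event_rate_hz * duration_s)
    if (n_ev > 0) {
      ev_t <- sort(stats::runif(n_ev, 0, duration_s))
      for (et in ev_t) {
        d <- t - et
        common <- common + ifelse(d < 0, 0, common_amp_dff * (d / 1.5) *
                                    exp(1 - d / 1.5))
      }
    }
    affected <- base * (1 + transient + common) +
      stats::rnorm(length(t), sd = noise_sd_f)
    reference <- base * (1 + common) + stats::rnorm(length(t), sd = noise_sd_f)
    list(affected = fluorescence_trace(t, affected),
         reference = fluorescence_trace(t, reference),
         truth = list(recovery_s = recovery_s, event_s = event_s,
                      peak_dff = peak_dff, tau_s = tau))
  })
}
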