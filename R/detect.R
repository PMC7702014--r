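# Seizure and population-spike detection. Seizures are paroxysmal events with
# amplitudes well above background that last >= 10 s at an event rate >= 2 Hz.
# Spikes are detected with a dual amplitude threshold (default 0.5 / 1 mV) on
# the absolute signal, with a biphasic-merge rule: two super-threshold peaks
# within the refractory period are one spike at the larger peak.

#' Detection parameters
#'
#' @param upper_v upper spike threshold (V); a candidate excursion must exceed
#'   it. Default 1 mV.
#' @param lower_v lower spike threshold (V); an excursion starts and ends at
#'   crossings of this level. Default 0.5 mV.
#' @param min_excursion_s,max_excursion_s admissible excursion span (default
#'   5-150 ms).
#' @param refractory_s minimum inter-spike separation; closer peaks are merged
#'   as one biphasic spike (default 100 ms).
#' @param seizure_offset_v seizure threshold offset above the background
#'   amplitude scale (V). Default 40 uV; values outside 20-65 uV trigger a
#'   warning but are accepted.
#' @param seizure_thresh_v absolute seizure threshold (V); when `NULL`
#'   (default) it is computed as `estimate_background(rec) + seizure_offset_v`.
#' @param bin_s raster bin width (default 0.5 s).
#' @param window_s raster sliding-window length (default 10 s).
#' @param min_seizure_s minimum seizure duration (default 10 s).
#' @param min_rate_hz minimum within-seizure super-threshold excursion rate
#'   (default 2 Hz).
#' @param gap_tol_s maximum quiescent gap bridged inside one seizure
#'   (default 2 s).
#' @return an object of class `detect_params`.
#' @export
detect_params <- function(upper_v = 1e-3, lower_v = 0.5e-3,
                          min_excursion_s = 0.005, max_excursion_s = 0.150,
                          refractory_s = 0.100, seizure_offset_v = 40e-6,
                          seizure_thresh_v = NULL, bin_s = 0.5, window_s = 10,
                          min_seizure_s = 10, min_rate_hz = 2, gap_tol_s = 2) {
  if (lower_v >= upper_v) stop("lower_v must be below upper_v", call. = FALSE)
  if (min_excursion_s >= max_excursion_s) {
    stop("min_excursion_s must be below max_excursion_s", call. = FALSE)
  }
  if (seizure_offset_v < 20e-6 || seizure_offset_v > 65e-6) {
    warning("seizure_offset_v outside the usual 20-65 uV range", call. = FALSE)
  }
  structure(list(upper_v = upper_v, lower_v = lower_v,
                 min_excursion_s = min_excursion_s,
                 max_excursion_s = max_excursion_s,
                 refractory_s = refractory_s,
                 seizure_offset_v = seizure_offset_v,
                 seizure_thresh_v = seizure_thresh_v, bin_s = bin_s,
                 window_s = window_s, min_seizure_s = min_seizure_s,
                 min_rate_hz = min_rate_hz, gap_tol_s = gap_tol_s),
            class = "detect_params")
}

#' Robust background amplitude of the non-paroxysmal signal
#'
#' Median absolute deviation (scaled by 1.4826, so it estimates the standard
#' deviation for Gaussian noise) of the samples lying outside the excluded
#' events.
#'
#' @param rec an [recording()].
#' @param exclusion optional [event_table()]; samples inside its rows (on the
#'   requested channel) are excluded.
#' @param channel channel id or index.
#' @return background amplitude scale in volts.
#' @export
estimate_background <- function(rec, exclusion = NULL, channel = 1) {
  x <- channel_data(rec, channel)
  keep <- rep(TRUE, length(x))
  if (!is.null(exclusion) && nrow(exclusion)) {
    ch <- if (is.character(channel)) channel else rec$channel_ids[channel]
    rows <- exclusion[exclusion$channel_id == ch | exclusion$channel_id == "", ,
                      drop = FALSE]
    t <- time_axis(rec)
    for (i in seq_len(nrow(rows))) {
      keep[t >= rows$start_s[i] & t < rows$end_s[i] + 1e-12] <- FALSE
    }
  }
  if (sum(keep) < rec$rate_hz) {
    stop("less than 1 s of data outside exclusions", call. = FALSE)
  }
  stats::mad(x[keep], constant = 1.4826)
}

.seizure_threshold <- function(rec, params, channel) {
  if (!is.null(params$seizure_thresh_v)) return(params$seizure_thresh_v)
  estimate_background(rec, channel = channel) + params$seizure_offset_v
}

# Runs of consecutive TRUE values as (start, end) sample indices.
.runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cbind(start = starts[r$values], end = ends[r$values])
}

# Merge index runs whose gaps are <= gap_n samples.
.merge_runs <- function(runs, gap_n) {
  if (nrow(runs) < 2) return(runs)
  keep_start <- runs[1, 1]
  out <- NULL
  cur <- runs[1, ]
  for (i in 2:nrow(runs)) {
    if (runs[i, 1] - cur[2] - 1 <= gap_n) {
      cur[2] <- runs[i, 2]
    } else {
      out <- rbind(out, cur)
      cur <- runs[i, ]
    }
  }
  rbind(out, cur)
}

#' Super-threshold raster counts per sliding window
#'
#' The recording is binned (`bin_s`, default 0.5 s); a bin is super-threshold
#' when the maximum absolute amplitude within it exceeds the seizure
#' threshold. Counts of super-threshold bins are reported per sliding window
#' (`window_s`, default 10 s) advanced by one bin.
#'
#' @param rec an [recording()] (filtered).
#' @param params a [detect_params()].
#' @param channel channel id or index.
#' @return data frame with `window_start_s` and `count`.
#' @export
raster_counts <- function(rec, params = detect_params(), channel = 1) {
  if (duration_s(rec) <= params$window_s) {
    stop("recording shorter than the raster window", call. = FALSE)
  }
  x <- abs(channel_data(rec, channel))
  thresh <- .seizure_threshold(rec, params, channel)
  bin_n <- round(params$bin_s * rec$rate_hz)
  n_bins <- floor(length(x) / bin_n)
  idx <- rep(seq_len(n_bins), each = bin_n)
  bin_max <- tapply(x[seq_len(n_bins * bin_n)], idx, max)
  super <- as.numeric(bin_max > thresh)
  bins_per_window <- round(params$window_s / params$bin_s)
  n_win <- n_bins - bins_per_window + 1
  counts <- cumsum(super)
  counts <- c(counts[bins_per_window],
              counts[seq.int(bins_per_window + 1, length.out = n_win - 1)] -
                counts[seq_len(n_win - 1)])
  data.frame(window_start_s = rec$t0_s + (seq_len(n_win) - 1) * params$bin_s,
             count = as.integer(counts))
}

# Super-threshold excursions: runs of |x| > thresh, with sub-refractory gaps
# merged (so the two lobes of one biphasic spike count once) and shorter runs
# than min_excursion_s discarded (rejects isolated noise samples).
.excursions <- function(x, rate_hz, thresh, params) {
  mask <- abs(x) > thresh
  if (!any(mask)) return(matrix(numeric(0), 0, 2))
  runs <- .runs(mask)
  # drop isolated noise crossings first, then merge the lobes of one spike
  dur <- (runs[, 2] - runs[, 1] + 1) / rate_hz
  runs <- runs[dur >= params$min_excursion_s, , drop = FALSE]
  if (!nrow(runs)) return(runs)
  .merge_runs(runs, round(params$refractory_s * rate_hz))
}

#' Detect seizures on every channel of a recording
#'
#' Candidate events are contiguous runs of super-threshold excursions with
#' quiescent gaps up to `gap_tol_s` bridged; events are kept when they last at
#' least `min_seizure_s` and their within-event excursion rate is at least
#' `min_rate_hz`. Population spikes are then attached with [detect_spikes()]
#' restricted to the event bounds.
#'
#' @param rec a filtered [recording()].
#' @param params a [detect_params()].
#' @return list of [seizure()] objects sorted by (channel, onset); empty list
#'   for quiescent input.
#' @export
detect_seizures <- function(rec, params = detect_params()) {
  out <- list()
  for (ci in seq_len(nrow(rec$samples))) {
    x <- rec$samples[ci, ]
    thresh <- .seizure_threshold(rec, params, ci)
    exc <- .excursions(x, rec$rate_hz, thresh, params)
    if (!nrow(exc)) next
    events <- .merge_runs(exc, round(params$gap_tol_s * rec$rate_hz))
    for (ei in seq_len(nrow(events))) {
      t_start <- rec$t0_s + (events[ei, 1] - 1) / rec$rate_hz
      t_end <- rec$t0_s + events[ei, 2] / rec$rate_hz
      dur <- t_end - t_start
      if (dur < params$min_seizure_s) next
      n_exc <- sum(exc[, 1] >= events[ei, 1] & exc[, 2] <= events[ei, 2])
      rate <- n_exc / dur
      if (rate < params$min_rate_hz) next
      train <- detect_spikes(rec, params, bounds = c(t_start, t_end),
                             channel = ci)
      out[[length(out) + 1]] <- seizure(rec$channel_ids[ci], t_start, t_end,
                                        train, mean_event_rate_hz = rate)
    }
  }
  out
}

#' Detect population spikes with a dual amplitude threshold
#'
#' A candidate is an excursion of the absolute signal that starts below
#' `lower_v`, exceeds `upper_v`, and returns below `lower_v`, with a total
#' span between `min_excursion_s` and `max_excursion_s`; its time is the time
#' of the peak absolute amplitude. Two candidate peaks within `refractory_s`
#' are merged into one spike at the larger peak (ties keep the earlier peak).
#'
#' @param rec a filtered [recording()].
#' @param params a [detect_params()].
#' @param bounds optional `c(start_s, end_s)` restricting detection.
#' @param channel channel id or index.
#' @return a [spike_train()]; empty when nothing crosses threshold.
#' @export
detect_spikes <- function(rec, params = detect_params(), bounds = NULL,
                          channel = 1) {
  x <- channel_data(rec, channel)
  offset <- 0L
  if (!is.null(bounds)) {
    i0 <- max(1L, floor((bounds[1] - rec$t0_s) * rec$rate_hz) + 1L)
    i1 <- min(length(x), ceiling((bounds[2] - rec$t0_s) * rec$rate_hz) + 1L)
    x <- x[i0:i1]
    offset <- i0 - 1L
  }
  ax <- abs(x)
  mask <- ax > params$lower_v
  if (!any(mask)) return(spike_train(numeric(0)))
  runs <- .runs(mask)
  span <- (runs[, 2] - runs[, 1] + 1) / rec$rate_hz
  peaks <- numeric(0)
  amps <- numeric(0)
  for (ri in seq_len(nrow(runs))) {
    if (span[ri] < params$min_excursion_s || span[ri] > params$max_excursion_s) next
    seg <- ax[runs[ri, 1]:runs[ri, 2]]
    if (max(seg) <= params$upper_v) next
    peak_i <- runs[ri, 1] + which.max(seg) - 1L
    peaks <- c(peaks, peak_i)
    amps <- c(amps, ax[peak_i])
  }
  if (!length(peaks)) return(spike_train(numeric(0)))
  # biphasic merge: repeatedly merge the closest pair within the refractory
  refr_n <- params$refractory_s * rec$rate_hz
  repeat {
    if (length(peaks) < 2) break
    gaps <- diff(peaks)
    close_i <- which(gaps <= refr_n)
    if (!length(close_i)) break
    i <- close_i[which.min(gaps[close_i])]
    keep <- if (amps[i + 1] > amps[i]) i + 1L else i  # tie -> earlier
    drop <- if (keep == i) i + 1L else i
    peaks <- peaks[-drop]
    amps <- amps[-drop]
  }
  spike_train(rec$t0_s + (peaks + offset - 1) / rec$rate_hz, amps,
              refractory_s = 0)
}

#' Apply manual spike overrides to a detected train
#'
#' Programmatic replacement for interactive spike correction: an override
#' table adds or removes spikes by time. Rows with `kind == "spike"` and
#' `value >= 0` (or `NA`) add a spike at `start_s` (with `value` as its
#' amplitude when positive); rows with `value < 0` remove the nearest detected
#' spike within `tol_s`.
#'
#' @param train a [spike_train()].
#' @param overrides an [event_table()] of spike rows.
#' @param tol_s matching tolerance for removals (default 10 ms).
#' @return the corrected [spike_train()].
#' @export
apply_spike_overrides <- function(train, overrides, tol_s = 0.01) {
  overrides <- overrides[overrides$kind == "spike", , drop = FALSE]
  times <- train$times_s
  amps <- train$peak_amp_v
  rem <- overrides[!is.na(overrides$value) & overrides$value < 0, , drop = FALSE]
  for (i in seq_len(nrow(rem))) {
    if (!length(times)) break
    d <- abs(times - rem$start_s[i])
    j <- which.min(d)
    if (d[j] <= tol_s) {
      times <- times[-j]
      amps <- amps[-j]
    }
  }
  add <- overrides[is.na(overrides$value) | overrides$value >= 0, , drop = FALSE]
  if (nrow(add)) {
    times <- c(times, add$start_s)
    amps <- c(amps, ifelse(is.na(add$value) | add$value == 0, NA_real_,
                           add$value))
    o <- order(times)
    times <- times[o]
    amps <- amps[o]
  }
  spike_train(times, amps, refractory_s = 0)
}
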