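# Time-resolved jitter: sliding-window jitter traces, spontaneous
# state-transition calling (mean + k.SD rule on a recording's own trace),
# Fano-factor variability summaries, and jitter-variability correlations.

new_jitter_trace <- function(window_start_s, jitter_pct, n_seizures,
                             window_s, step_s) {
  out <- data.frame(window_start_s = window_start_s, jitter_pct = jitter_pct,
                    n_seizures_in_window = as.integer(n_seizures))
  attr(out, "window_s") <- window_s
  attr(out, "step_s") <- step_s
  class(out) <- c("jitter_trace", "data.frame")
  out
}

# Lazily filled pairwise jitter cache over a fixed seizure list.
.pair_cache <- function(trains) {
  n <- length(trains)
  m <- matrix(NA_real_, n, n)
  usable <- vapply(trains, function(tr) length(tr$times_s) >= 2, logical(1))
  function(i, j) {
    if (i == j) return(0)
    if (!usable[i] || !usable[j]) return(NA_real_)
    if (is.na(m[i, j])) {
      v <- jitter(trains[[i]], trains[[j]])$jitter_pct
      m[i, j] <<- v
      m[j, i] <<- v
    }
    m[i, j]
  }
}

.window_mean_jitter <- function(members, get_j) {
  if (length(members) < 2) return(NA_real_)
  vals <- numeric(0)
  for (ii in seq_along(members)[-length(members)]) {
    for (jj in (ii + 1):length(members)) {
      vals <- c(vals, get_j(members[ii], members[jj]))
    }
  }
  mean(vals, na.rm = TRUE)
}

#' Sliding-window jitter trace
#'
#' For each time window the jitter is the mean of the optimal-alignment
#' pairwise jitters over all unique pairs of seizures whose onsets fall in the
#' window (`NA` with fewer than 2 seizures). Defaults mirror a 1 h window
#' advanced every 10 min.
#'
#' @param seizures time-ordered list of [seizure()] objects.
#' @param window_s window length in seconds (default 3600).
#' @param step_s window advance in seconds (default 600).
#' @param t_start,t_end optional trace span; default first/last seizure onset.
#' @return a `jitter_trace` data frame with `window_start_s`, `jitter_pct`,
#'   `n_seizures_in_window`.
#' @export
windowed_jitter <- function(seizures, window_s = 3600, step_s = 600,
                            t_start = NULL, t_end = NULL) {
  if (window_s <= 0 || step_s <= 0) {
    stop("window_s and step_s must be positive", call. = FALSE)
  }
  onsets <- seizure_onsets(seizures)
  if (is.unsorted(onsets)) stop("seizures must be time-ordered", call. = FALSE)
  if (is.null(t_start)) t_start <- min(onsets)
  if (is.null(t_end)) t_end <- max(onsets)
  starts <- seq(t_start, max(t_start, t_end - window_s + step_s), by = step_s)
  trains <- lapply(seizures, `[[`, "spikes")
  get_j <- .pair_cache(trains)
  vals <- numeric(length(starts))
  counts <- integer(length(starts))
  for (k in seq_along(starts)) {
    members <- which(onsets >= starts[k] & onsets < starts[k] + window_s)
    counts[k] <- length(members)
    vals[k] <- .window_mean_jitter(members, get_j)
  }
  new_jitter_trace(starts, vals, counts, window_s, step_s)
}

#' Event-count-windowed jitter trace
#'
#' Windows are consecutive runs of `events_per_window` seizures, advanced one
#' seizure per step, so each step exchanges a single event. The trace point
#' time is the onset of the first seizure in the run.
#'
#' @param seizures time-ordered list of [seizure()] objects.
#' @param events_per_window seizures per window (default 2).
#' @return a `jitter_trace` data frame.
#' @export
event_windowed_jitter <- function(seizures, events_per_window = 2) {
  m <- as.integer(events_per_window)
  if (m < 2) stop("events_per_window must be at least 2", call. = FALSE)
  n <- length(seizures)
  if (n < m) stop("fewer seizures than events_per_window", call. = FALSE)
  onsets <- seizure_onsets(seizures)
  if (is.unsorted(onsets)) stop("seizures must be time-ordered", call. = FALSE)
  trains <- lapply(seizures, `[[`, "spikes")
  get_j <- .pair_cache(trains)
  starts <- onsets[seq_len(n - m + 1)]
  vals <- vapply(seq_len(n - m + 1), function(k) {
    .window_mean_jitter(k:(k + m - 1), get_j)
  }, numeric(1))
  new_jitter_trace(starts, vals, rep(m, length(starts)),
                   window_s = NA_real_, step_s = NA_real_)
}

#' Bin a jitter trace into box-plot-ready summaries
#'
#' @param trace a `jitter_trace`.
#' @param bin_s bin width in seconds (default 300, i.e. 5 min).
#' @return data frame per bin: `bin_start_s`, `n`, `median`, `q25`, `q75`,
#'   `min`, `max` over the non-missing trace points in the bin.
#' @export
bin_trace <- function(trace, bin_s = 300) {
  if (!nrow(trace)) stop("empty trace", call. = FALSE)
  ok <- !is.na(trace$jitter_pct)
  t <- trace$window_start_s[ok]
  v <- trace$jitter_pct[ok]
  bin <- floor((t - min(trace$window_start_s)) / bin_s)
  do.call(rbind, lapply(sort(unique(bin)), function(b) {
    x <- v[bin == b]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    data.frame(bin_start_s = min(trace$window_start_s) + b * bin_s,
               n = length(x), median = q[2], q25 = q[1], q75 = q[3],
               min = min(x), max = max(x))
  }))
}

#' Call spontaneous state transitions from a jitter trace
#'
#' The calling threshold is `mean + k_sd * SD` (sample SD) of all non-missing
#' jitter values of the trace itself. Maximal runs of consecutive
#' super-threshold windows become one transition each; missing points break
#' runs. A constant trace (SD = 0) yields no transitions by definition.
#'
#' @param trace a `jitter_trace` with at least 3 non-missing points.
#' @param k_sd threshold multiplier (default 2).
#' @return data frame of class `transition_events`: `onset_s` (start of the
#'   first super-threshold window), `offset_s` (end of the last),
#'   `peak_jitter_pct`, and `change_time_s`, the point estimate of when the
#'   waveform changed - the centroid of the run's window centres weighted by
#'   the jitter excess above threshold (the window mixing the two waveforms
#'   most evenly carries the largest excess). The threshold used is attached
#'   as attribute `threshold`.
#' @export
detect_transitions <- function(trace, k_sd = 2.0) {
  v <- trace$jitter_pct
  ok <- !is.na(v)
  if (sum(ok) == 0) stop("all trace points missing", call. = FALSE)
  if (sum(ok) < 3) stop("need at least 3 non-missing trace points", call. = FALSE)
  mu <- mean(v[ok])
  sdv <- stats::sd(v[ok])
  thresh <- mu + k_sd * sdv
  window_s <- attr(trace, "window_s")
  if (is.null(window_s) || is.na(window_s)) {
    window_s <- stats::median(diff(trace$window_start_s))
  }
  super <- ok & v > thresh & sdv > 0
  out <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                    peak_jitter_pct = numeric(0), change_time_s = numeric(0))
  if (any(super)) {
    runs <- .runs(super)
    out <- do.call(rbind, lapply(seq_len(nrow(runs)), function(ri) {
      idx <- runs[ri, 1]:runs[ri, 2]
      centers <- trace$window_start_s[idx] + window_s / 2
      excess <- v[idx] - thresh
      data.frame(onset_s = trace$window_start_s[runs[ri, 1]],
                 offset_s = trace$window_start_s[runs[ri, 2]] + window_s,
                 peak_jitter_pct = max(v[idx]),
                 change_time_s = sum(excess * centers) / sum(excess))
    }))
  }
  attr(out, "threshold") <- thresh
  class(out) <- c("transition_events", "data.frame")
  out
}

#' Within-state versus cross-state jitter samples
#'
#' Transitions split the recording into stable-state segments. Within-state
#' jitters are the pairwise jitters among seizures inside one segment (pooled
#' over segments); cross-state jitters pair seizures on opposite sides of a
#' transition (adjacent segments). Seizures whose onsets fall inside a
#' transition interval belong to neither sample.
#'
#' @param seizures time-ordered list of [seizure()] objects.
#' @param transitions a `transition_events` data frame.
#' @param max_per_side cap on seizures taken from each side of a transition
#'   for the cross sample (default `Inf`, i.e. all).
#' @return list with numeric vectors `within` and `cross` (either may be
#'   empty when a segment holds fewer than 2 usable seizures).
#' @export
state_vs_transition_jitter <- function(seizures, transitions,
                                       max_per_side = Inf) {
  onsets <- seizure_onsets(seizures)
  trains <- lapply(seizures, `[[`, "spikes")
  get_j <- .pair_cache(trains)
  bounds <- c(-Inf, as.vector(t(as.matrix(transitions[, c("onset_s", "offset_s")]))),
              Inf)
  n_seg <- nrow(transitions) + 1
  segments <- lapply(seq_len(n_seg), function(si) {
    lo <- bounds[2 * si - 1]
    hi <- bounds[2 * si]
    which(onsets >= lo & onsets < hi)
  })
  within <- unlist(lapply(segments, function(members) {
    if (length(members) < 2) return(numeric(0))
    vals <- numeric(0)
    for (ii in seq_along(members)[-length(members)]) {
      for (jj in (ii + 1):length(members)) {
        vals <- c(vals, get_j(members[ii], members[jj]))
      }
    }
    vals
  }))
  cross <- unlist(lapply(seq_len(nrow(transitions)), function(ti) {
    pre <- segments[[ti]]
    post <- segments[[ti + 1]]
    if (is.finite(max_per_side)) {
      pre <- utils::tail(pre, max_per_side)
      post <- utils::head(post, max_per_side)
    }
    if (!length(pre) || !length(post)) return(numeric(0))
    as.vector(outer(pre, post, Vectorize(get_j)))
  }))
  list(within = as.numeric(stats::na.omit(within)),
       cross = as.numeric(stats::na.omit(cross)))
}

#' Fano factor (variance over mean)
#'
#' Sample variance (n - 1 denominator) divided by the mean; applied to
#' seizure durations and inter-seizure intervals as a dispersion summary.
#'
#' @param values numeric vector, at least 2 values with positive mean.
#' @return the Fano factor.
#' @export
fano <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  m <- mean(values)
  if (!is.finite(m) || m <= 0) stop("mean must be positive", call. = FALSE)
  stats::var(values) / m
}

#' Correlation between windowed jitter and seizure-timing variability
#'
#' For each window of the trace, the standard deviation of the seizure
#' durations (`stat = "duration_sd"`) or of the inter-seizure onset intervals
#' (`stat = "interval_sd"`) among seizures whose onsets fall in the window is
#' paired with the window's jitter; Pearson correlation is computed over
#' pairwise-complete windows.
#'
#' @param trace a `jitter_trace` produced by [windowed_jitter()].
#' @param seizures the seizure list the trace was computed from.
#' @param stat which variability statistic to correlate against.
#' @return list with `r`, `p` (two-sided), and `n` (paired windows).
#' @export
jitter_variability_correlation <- function(trace, seizures,
                                           stat = c("duration_sd",
                                                    "interval_sd")) {
  stat <- match.arg(stat)
  window_s <- attr(trace, "window_s")
  if (is.null(window_s) || is.na(window_s)) {
    stop("trace must carry a time window (from windowed_jitter)", call. = FALSE)
  }
  onsets <- seizure_onsets(seizures)
  durations <- seizure_ends(seizures) - onsets
  sd_vals <- vapply(seq_len(nrow(trace)), function(k) {
    members <- which(onsets >= trace$window_start_s[k] &
                       onsets < trace$window_start_s[k] + window_s)
    if (stat == "duration_sd") {
      if (length(members) < 2) return(NA_real_)
      stats::sd(durations[members])
    } else {
      if (length(members) < 3) return(NA_real_)
      stats::sd(diff(onsets[members]))
    }
  }, numeric(1))
  ok <- !is.na(sd_vals) & !is.na(trace$jitter_pct)
  if (sum(ok) < 3) stop("fewer than 3 paired windows", call. = FALSE)
  ct <- stats::cor.test(trace$jitter_pct[ok], sd_vals[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}
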