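#' szjitter: seizure variability analysis for in-vitro LFP recordings
#'
#' Analysis stack for spontaneous epileptiform activity recorded
#' extracellularly from in-vitro preparations (organotypic hippocampal
#' cultures on microwires or multi-electrode arrays): preprocessing,
#' population-spike and seizure detection, the inter-spike-interval jitter
#' statistic, windowed jitter evolution with state-transition calling,
#' Fano-factor summaries, calcium delta-F/F analysis, and a synthetic
#' ground-truth signal generator.
#'
#' @importFrom stats approx cor.test mad median quantile rnorm rgamma runif sd var fft
#' @importFrom utils read.csv write.csv packageVersion modifyList
#' @keywords internal
"_PACKAGE"

# ---- Recording ---------------------------------------------------------------

#' Construct a multichannel LFP recording
#'
#' A recording holds uniformly sampled voltage traces, one row per channel.
#' Amplitudes are stored in volts throughout the package; unit conversion
#' happens at the I/O boundary (see [read_recording()]). Sample `k` (0-based)
#' corresponds to time `t0_s + k / rate_hz`.
#'
#' @param samples numeric matrix, channels x timepoints (volts), or a numeric
#'   vector for a single channel.
#' @param rate_hz sampling rate in samples per second (> 0).
#' @param t0_s time of the first sample, seconds.
#' @param channel_ids character vector of channel names; defaults to
#'   `"ch1"`, `"ch2"`, ...
#' @param meta named list of free-form annotations (e.g. modality,
#'   media-exchange time).
#' @return an object of class `lfp_recording`.
#' @export
recording <- function(samples, rate_hz, t0_s = 0, channel_ids = NULL,
                      meta = list()) {
  if (is.null(dim(samples))) samples <- matrix(as.numeric(samples), nrow = 1)
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (!is.numeric(rate_hz) || length(rate_hz) != 1 || !is.finite(rate_hz) ||
      rate_hz <= 0) {
    stop("rate_hz must be a single positive number", call. = FALSE)
  }
  if (nrow(samples) < 1) stop("recording has no channels", call. = FALSE)
  if (is.null(channel_ids)) channel_ids <- paste0("ch", seq_len(nrow(samples)))
  channel_ids <- as.character(channel_ids)
  if (length(channel_ids) != nrow(samples)) {
    stop("channel_ids length must match the number of channels", call. = FALSE)
  }
  structure(
    list(samples = samples, rate_hz = as.numeric(rate_hz),
         t0_s = as.numeric(t0_s), channel_ids = channel_ids, meta = meta),
    class = "lfp_recording"
  )
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> %d channel(s) x %d samples @ %g Hz (%.3f s)\n",
              nrow(x$samples), ncol(x$samples), x$rate_hz,
              ncol(x$samples) / x$rate_hz))
  cat(sprintf("  t0 = %g s; channels: %s\n", x$t0_s,
              paste(x$channel_ids, collapse = ", ")))
  invisible(x)
}

#' Number of samples / duration of a recording
#' @param rec an `lfp_recording`.
#' @return `n_samples()`: integer count; `duration_s()`: duration in seconds.
#' @export
n_samples <- function(rec) ncol(rec$samples)

#' @rdname n_samples
#' @export
duration_s <- function(rec) ncol(rec$samples) / rec$rate_hz

#' Time axis of a recording
#' @param rec an `lfp_recording`.
#' @return numeric vector of sample times in seconds.
#' @export
time_axis <- function(rec) rec$t0_s + (seq_len(ncol(rec$samples)) - 1) / rec$rate_hz

#' Extract one channel as a numeric vector
#' @param rec an `lfp_recording`.
#' @param channel channel id (character) or index.
#' @return numeric vector of samples (volts).
#' @export
channel_data <- function(rec, channel = 1) {
  if (is.character(channel)) {
    channel <- match(channel, rec$channel_ids)
    if (is.na(channel)) stop("unknown channel id", call. = FALSE)
  }
  rec$samples[channel, ]
}

# ---- EventTable --------------------------------------------------------------

.event_kinds <- c("spike", "seizure", "transition")

#' Construct an event table
#'
#' The shared tabular container for detected events. Rows are sorted by
#' `(channel_id, start_s)`. Spikes are instants (`start_s == end_s`, the peak
#' time); seizures are half-open intervals `[start_s, end_s)`.
#'
#' @param channel_id character vector.
#' @param start_s,end_s numeric event bounds in seconds (`start_s <= end_s`).
#' @param kind one of `"spike"`, `"seizure"`, `"transition"` per row.
#' @param value optional numeric annotation per row (`NA` allowed).
#' @return a `data.frame` of class `event_table`.
#' @export
event_table <- function(channel_id = character(), start_s = numeric(),
                        end_s = numeric(), kind = character(),
                        value = rep(NA_real_, length(start_s))) {
  tbl <- data.frame(channel_id = as.character(channel_id),
                    start_s = as.numeric(start_s),
                    end_s = as.numeric(end_s),
                    kind = as.character(kind),
                    value = as.numeric(value),
                    stringsAsFactors = FALSE)
  validate_event_table(tbl)
}

validate_event_table <- function(tbl) {
  req <- c("channel_id", "start_s", "end_s", "kind", "value")
  missing_cols <- setdiff(req, names(tbl))
  if (length(missing_cols)) {
    stop("event table missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  tbl <- tbl[req]
  bad <- which(!tbl$kind %in% .event_kinds)
  if (length(bad)) stop("invalid event kind at row ", bad[1], call. = FALSE)
  bad <- which(tbl$start_s > tbl$end_s)
  if (length(bad)) stop("start_s > end_s at row ", bad[1], call. = FALSE)
  bad <- which(tbl$kind == "spike" & tbl$start_s != tbl$end_s)
  if (length(bad)) {
    stop("spike rows must have start_s == end_s (row ", bad[1], ")",
         call. = FALSE)
  }
  tbl <- tbl[order(tbl$channel_id, tbl$start_s), , drop = FALSE]
  rownames(tbl) <- NULL
  class(tbl) <- c("event_table", "data.frame")
  tbl
}

#' Subset an event table by kind
#' @param tbl an `event_table`.
#' @param kind event kind to keep.
#' @return an `event_table` with only the requested rows.
#' @export
events_of_kind <- function(tbl, kind) {
  validate_event_table(as.data.frame(tbl)[tbl$kind == kind, , drop = FALSE])
}

# ---- SpikeTrain / Seizure ----------------------------------------------------

#' Construct a population-spike train
#'
#' Ordered population-spike peak times with peak magnitudes, as produced by
#' [detect_spikes()] for one seizure. Consecutive spikes must be separated by
#' more than the detector's refractory period.
#'
#' @param times_s strictly increasing spike peak times (seconds).
#' @param peak_amp_v peak amplitude magnitudes (volts), same length; optional.
#' @param refractory_s minimum separation enforced by the invariant check
#'   (default 0.1 s); set to 0 to skip.
#' @return an object of class `spike_train`.
#' @export
spike_train <- function(times_s, peak_amp_v = rep(NA_real_, length(times_s)),
                        refractory_s = 0.1) {
  times_s <- as.numeric(times_s)
  peak_amp_v <- as.numeric(peak_amp_v)
  if (length(peak_amp_v) != length(times_s)) {
    stop("times_s and peak_amp_v must have equal length", call. = FALSE)
  }
  if (length(times_s) > 1) {
    d <- diff(times_s)
    if (any(d <= 0)) stop("spike times must be strictly increasing", call. = FALSE)
    if (refractory_s > 0 && any(d <= refractory_s - 1e-12)) {
      stop("spike separation violates the refractory period", call. = FALSE)
    }
  }
  structure(list(times_s = times_s, peak_amp_v = peak_amp_v),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes", length(x$times_s)))
  if (length(x$times_s)) {
    cat(sprintf(" over [%.3f, %.3f] s", min(x$times_s), max(x$times_s)))
  }
  cat("\n")
  invisible(x)
}

#' @export
length.spike_train <- function(x) length(x$times_s)

#' Construct a seizure (detected paroxysmal event)
#'
#' @param channel_id channel the event was detected on.
#' @param start_s,end_s event bounds, seconds (`end_s > start_s`).
#' @param spikes a [spike_train()] whose times lie within `[start_s, end_s]`.
#' @param mean_event_rate_hz mean super-threshold event rate within the
#'   seizure; computed from `spikes` if omitted.
#' @return an object of class `seizure`.
#' @export
seizure <- function(channel_id, start_s, end_s, spikes,
                    mean_event_rate_hz = NULL) {
  stopifnot(inherits(spikes, "spike_train"))
  if (end_s <= start_s) stop("seizure must have positive duration", call. = FALSE)
  n <- length(spikes$times_s)
  if (n && (min(spikes$times_s) < start_s - 1e-9 ||
            max(spikes$times_s) > end_s + 1e-9)) {
    stop("spike times must lie within the seizure bounds", call. = FALSE)
  }
  if (is.null(mean_event_rate_hz)) {
    mean_event_rate_hz <- n / (end_s - start_s)
  }
  structure(list(channel_id = as.character(channel_id),
                 start_s = as.numeric(start_s), end_s = as.numeric(end_s),
                 spikes = spikes,
                 mean_event_rate_hz = as.numeric(mean_event_rate_hz)),
            class = "seizure")
}

#' @export
print.seizure <- function(x, ...) {
  cat(sprintf("<seizure> %s [%.2f, %.2f] s, %d spikes, %.2f Hz\n",
              x$channel_id, x$start_s, x$end_s, length(x$spikes$times_s),
              x$mean_event_rate_hz))
  invisible(x)
}

#' Onset and end times of a list of seizures
#'
#' @param seizures list of [seizure()] objects.
#' @return numeric vector of start (or end) times in seconds.
#' @export
seizure_onsets <- function(seizures) vapply(seizures, `[[`, numeric(1), "start_s")

#' @rdname seizure_onsets
#' @export
seizure_ends <- function(seizures) vapply(seizures, `[[`, numeric(1), "end_s")

#' Convert a list of seizures (and their spikes) to an event table
#' @param seizures list of [seizure()] objects.
#' @param include_spikes also emit one spike row per population spike.
#' @return an `event_table`; seizure rows carry the spike count in `value`,
#'   spike rows carry the peak amplitude (volts).
#' @export
seizures_to_events <- function(seizures, include_spikes = TRUE) {
  rows <- lapply(seizures, function(sz) {
    out <- data.frame(channel_id = sz$channel_id, start_s = sz$start_s,
                      end_s = sz$end_s, kind = "seizure",
                      value = length(sz$spikes$times_s),
                      stringsAsFactors = FALSE)
    if (include_spikes && length(sz$spikes$times_s)) {
      out <- rbind(out, data.frame(channel_id = sz$channel_id,
                                   start_s = sz$spikes$times_s,
                                   end_s = sz$spikes$times_s, kind = "spike",
                                   value = sz$spikes$peak_amp_v,
                                   stringsAsFactors = FALSE))
    }
    out
  })
  validate_event_table(do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

#' Reconstruct seizures from an event table
#'
#' Inverse of [seizures_to_events()]: groups spike rows into the seizure rows
#' that contain them (per channel).
#'
#' @param tbl an `event_table` with `seizure` (and optionally `spike`) rows.
#' @return list of [seizure()] objects ordered by onset.
#' @export
events_to_seizures <- function(tbl) {
  tbl <- validate_event_table(as.data.frame(tbl))
  sz <- tbl[tbl$kind == "seizure", , drop = FALSE]
  sp <- tbl[tbl$kind == "spike", , drop = FALSE]
  out <- lapply(seq_len(nrow(sz)), function(i) {
    row <- sz[i, ]
    sel <- sp$channel_id == row$channel_id &
      sp$start_s >= row$start_s - 1e-9 & sp$start_s <= row$end_s + 1e-9
    seizure(row$channel_id, row$start_s, row$end_s,
            spike_train(sp$start_s[sel], sp$value[sel], refractory_s = 0))
  })
  out[order(vapply(out, `[[`, numeric(1), "start_s"))]
}
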