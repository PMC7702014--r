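# Preprocessing: Butterworth filtering (applied zero-phase), anti-aliased
# resampling, and signal-to-noise summaries. Zero-phase application
# (forward-backward) is deliberate: downstream jitter is a timing statistic
# and phase distortion of spike peaks would bias it. The effective magnitude
# response is therefore |H(f)|^2 of the designed filter.

#' Specify a Butterworth filter
#'
#' @param kind `"bandstop"`, `"highpass"`, or `"bandpass"`.
#' @param order filter order of the designed (one-pass) Butterworth filter.
#' @param edges_hz one (highpass) or two ordered (bandpass/bandstop) corner
#'   frequencies in Hz; must lie strictly inside `(0, rate_hz / 2)` of the
#'   recording the filter is applied to.
#' @param zero_phase apply forward-backward (default `TRUE`).
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("bandstop", "highpass", "bandpass"),
                        order = 4, edges_hz, zero_phase = TRUE) {
  kind <- match.arg(kind)
  edges_hz <- as.numeric(edges_hz)
  n_edges <- if (kind == "highpass") 1L else 2L
  if (length(edges_hz) != n_edges) {
    stop(kind, " filter needs ", n_edges, " edge(s)", call. = FALSE)
  }
  if (any(edges_hz <= 0) || is.unsorted(edges_hz, strictly = TRUE) && n_edges == 2) {
    stop("filter edges must be positive and ordered", call. = FALSE)
  }
  if (order < 1 || order != round(order)) stop("order must be a positive integer",
                                               call. = FALSE)
  structure(list(kind = kind, order = as.integer(order), edges_hz = edges_hz,
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' Built-in filter presets
#'
#' * `mea_notch`: 4th-order Butterworth band-stop with a 58-62 Hz stop band
#'   (mains-noise removal around 60 Hz).
#' * `mea_highpass`: 4th-order Butterworth high-pass at 3 Hz (removes DC and
#'   slow mechanical drift).
#' * `smw_band`: band-pass from 1 Hz to `min(3000, 0.45 * rate_hz)` Hz,
#'   mirroring a 1 Hz - 3 kHz acquisition band.
#'
#' @param name preset name.
#' @param rate_hz sampling rate the preset will be applied at (needed for
#'   `smw_band`'s upper edge).
#' @return a [filter_spec()].
#' @export
filter_preset <- function(name = c("mea_notch", "mea_highpass", "smw_band"),
                          rate_hz = NULL) {
  name <- match.arg(name)
  switch(name,
    mea_notch = filter_spec("bandstop", 4, c(58, 62)),
    mea_highpass = filter_spec("highpass", 4, 3),
    smw_band = {
      if (is.null(rate_hz)) stop("smw_band preset needs rate_hz", call. = FALSE)
      filter_spec("bandpass", 4, c(1, min(3000, 0.45 * rate_hz)))
    })
}

# Butterworth design in zero-pole-gain form. This mirrors the analogue
# prototype -> band transform -> bilinear transform path but stops before the
# expansion into a single numerator/denominator polynomial: for narrow-band
# designs (e.g. a 58-62 Hz stop band at 6 kHz) that expansion is numerically
# singular (roots of the expanded polynomial stray outside the unit circle),
# so the filter is kept factored and applied as a cascade of second-order
# sections instead.
.butter_zpg <- function(order, w, type) {
  in_stopband_form <- type %in% c("stop", "high")
  big_t <- 2
  w_warp <- 2 / big_t * tan(pi * w / big_t)
  pole <- exp(1i * pi * (2 * seq_len(order) + order - 1) / (2 * order))
  if (order %% 2 == 1) pole[(order + 1) / 2] <- -1
  zpg <- signal::Zpg(zero = numeric(0), pole = pole, gain = 1)
  zpg <- signal::sftrans(zpg, W = w_warp, stop = in_stopband_form)
  signal::bilinear(zpg, T = big_t)
}

# Split a conjugate-symmetric root set into conjugate pairs / leftover reals.
# Each upper-half-plane root is paired with its own conjugate so the pair
# products below are exactly real.
.conj_pairs <- function(v, tol = 1e-8) {
  is_real <- abs(Im(v)) <= tol * pmax(1, Mod(v))
  re <- sort(Re(v[is_real]))
  up <- v[!is_real & Im(v) > 0]
  pairs <- lapply(up, function(z) c(z, Conj(z)))
  while (length(re) >= 2) {
    pairs[[length(pairs) + 1]] <- complex(real = re[1:2], imaginary = 0)
    re <- re[-(1:2)]
  }
  if (length(re) == 1) pairs[[length(pairs) + 1]] <- complex(real = re, imaginary = 0)
  pairs
}

# Factor a z-plane zero/pole/gain filter into second-order sections (biquads).
# Pole pairs are ordered from lowest to highest Q, and each is matched with the
# nearest remaining zero pair; the overall gain goes on the first section.
.zpg_to_sos <- function(zpg) {
  p_pairs <- .conj_pairs(zpg$pole)
  z_pairs <- .conj_pairs(zpg$zero)
  if (length(z_pairs) > length(p_pairs)) {
    stop("more zeros than poles in filter design", call. = FALSE)
  }
  p_pairs <- p_pairs[order(vapply(p_pairs, function(p) max(Mod(p)), numeric(1)))]
  sections <- vector("list", length(p_pairs))
  for (k in rev(seq_along(p_pairs))) {    # highest-Q pole pair chooses first
    pp <- p_pairs[[k]]
    zz <- complex(0)
    if (length(z_pairs)) {
      d <- vapply(z_pairs, function(z) min(Mod(z[1] - pp)), numeric(1))
      pick <- which.min(d)
      zz <- z_pairs[[pick]]
      z_pairs <- z_pairs[-pick]
    }
    poly2 <- function(r) {
      if (length(r) == 0) return(1)
      if (length(r) == 1) return(Re(c(1, -r)))
      Re(c(1, -(r[1] + r[2]), r[1] * r[2]))
    }
    sections[[k]] <- list(b = poly2(zz), a = poly2(pp),
                          max_pole_r = max(Mod(pp)))
  }
  sections[[1]]$b <- sections[[1]]$b * Re(zpg$gain)
  sections
}

.design_sos <- function(order, edges_hz, type, rate_hz) {
  nyq <- rate_hz / 2
  if (any(edges_hz >= nyq)) {
    stop("filter edge at or above Nyquist (", nyq, " Hz)", call. = FALSE)
  }
  zpg <- .butter_zpg(order, edges_hz / nyq, type)
  list(sos = .zpg_to_sos(zpg), zpg = zpg)
}

.spec_type <- function(kind) {
  switch(kind, bandstop = "stop", highpass = "high", bandpass = "pass",
         lowpass = "low")
}

.sos_pass <- function(sections, x) {
  for (sec in sections) {
    x <- as.numeric(signal::filter(sec$b, sec$a, x))
  }
  x
}

# Zero-phase (forward-backward) application of a second-order-section cascade.
# The signal is extended at both ends by odd reflection, long enough for the
# slowest pole's transient to decay, so start-up transients land in the
# discarded padding rather than in the output.
.sos_filtfilt <- function(sections, x) {
  n <- length(x)
  r_max <- max(vapply(sections, function(s) s$max_pole_r, numeric(1)))
  pad <- ceiling(9 / max(1 - r_max, 1e-6))
  pad <- max(100L, min(n - 1L, pad))
  left <- 2 * x[1] - x[(pad + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - pad)]
  y <- c(left, x, right)
  y <- .sos_pass(sections, y)
  y <- rev(.sos_pass(sections, rev(y)))
  y[(pad + 1):(pad + n)]
}

#' Apply a filter to all channels of a recording
#'
#' The designed Butterworth filter is factored into second-order sections and
#' applied as a cascade, which stays numerically stable even for narrow-band
#' designs whose single-polynomial form is ill-conditioned. For DC-rejecting
#' kinds (highpass, bandpass) the channel mean is subtracted first, so a
#' constant input maps to exactly zero.
#'
#' @param rec an [recording()].
#' @param spec a [filter_spec()] or a preset name accepted by
#'   [filter_preset()].
#' @return a filtered recording with identical shape, rate and metadata.
#' @export
apply_filter <- function(rec, spec) {
  stopifnot(inherits(rec, "lfp_recording"))
  if (is.character(spec)) spec <- filter_preset(spec, rate_hz = rec$rate_hz)
  stopifnot(inherits(spec, "filter_spec"))
  design <- .design_sos(spec$order, spec$edges_hz, .spec_type(spec$kind),
                        rec$rate_hz)
  dc_reject <- spec$kind %in% c("highpass", "bandpass")
  out <- rec
  for (i in seq_len(nrow(rec$samples))) {
    x <- rec$samples[i, ]
    if (dc_reject) x <- x - mean(x)
    out$samples[i, ] <- if (spec$zero_phase) .sos_filtfilt(design$sos, x)
    else .sos_pass(design$sos, x)
  }
  out
}

#' Magnitude response of a filter spec as applied
#'
#' Evaluates `|H(f)|` of the designed Butterworth filter at the given
#' frequencies, squared when the spec is zero-phase (forward-backward
#' application squares the magnitude response). The response is evaluated
#' directly from the factored zero/pole/gain form, which is exact even for
#' narrow-band designs.
#'
#' @param spec a [filter_spec()].
#' @param freq_hz frequencies to evaluate at (Hz).
#' @param rate_hz sampling rate (Hz).
#' @return numeric vector of linear gains.
#' @export
filter_gain <- function(spec, freq_hz, rate_hz) {
  design <- .design_sos(spec$order, spec$edges_hz, .spec_type(spec$kind),
                        rate_hz)
  zpg <- design$zpg
  g <- vapply(freq_hz, function(f) {
    e <- exp(1i * 2 * pi * f / rate_hz)
    num <- prod(Mod(e - zpg$zero))
    den <- prod(Mod(e - zpg$pole))
    Mod(zpg$gain) * num / den
  }, numeric(1))
  if (spec$zero_phase) g^2 else g
}

#' Downsample a recording with anti-alias filtering
#'
#' An 8th-order Butterworth low-pass at `0.4 * target_hz` is applied
#' zero-phase, then the signal is decimated (integer ratios) or linearly
#' interpolated onto the new sample grid. Duration is preserved to within one
#' output sample.
#'
#' @param rec an [recording()].
#' @param target_hz new sampling rate, `< rec$rate_hz`.
#' @return a recording at `target_hz`.
#' @export
downsample <- function(rec, target_hz) {
  stopifnot(inherits(rec, "lfp_recording"))
  if (!is.numeric(target_hz) || target_hz <= 0 || target_hz >= rec$rate_hz) {
    stop("target_hz must be positive and below the current rate", call. = FALSE)
  }
  aa <- .design_sos(8, 0.4 * target_hz, "low", rec$rate_hz)
  ratio <- rec$rate_hz / target_hz
  int_ratio <- abs(ratio - round(ratio)) < 1e-9
  n_new <- floor(ncol(rec$samples) / ratio)
  t_old <- time_axis(rec)
  t_new <- rec$t0_s + (seq_len(n_new) - 1) / target_hz
  new_samples <- matrix(0, nrow(rec$samples), n_new)
  for (i in seq_len(nrow(rec$samples))) {
    x <- .sos_filtfilt(aa$sos, rec$samples[i, ])
    new_samples[i, ] <- if (int_ratio) {
      x[seq(1, by = round(ratio), length.out = n_new)]
    } else {
      stats::approx(t_old, x, xout = t_new)$y
    }
  }
  out <- recording(new_samples, rate_hz = target_hz, t0_s = rec$t0_s,
                   channel_ids = rec$channel_ids, meta = rec$meta)
  out
}

#' Signal-to-noise ratio in decibels
#'
#' `10 * log10(P_signal / P_noise)` where each power is the mean squared
#' amplitude, after removing the mean, over the pooled samples of the given
#' windows. Windows are half-open `[start_s, end_s)` in recording time.
#'
#' @param rec an [recording()].
#' @param signal_windows,noise_windows lists of `c(start_s, end_s)` pairs (or
#'   a 2-column matrix).
#' @param channel channel id or index (default first).
#' @return SNR in dB.
#' @export
snr_db <- function(rec, signal_windows, noise_windows, channel = 1) {
  x <- channel_data(rec, channel)
  pool <- function(windows) {
    if (is.matrix(windows)) windows <- asplit(windows, 1)
    if (!length(windows)) stop("empty window list", call. = FALSE)
    idx <- unlist(lapply(windows, function(w) {
      i0 <- floor((w[1] - rec$t0_s) * rec$rate_hz) + 1
      i1 <- ceiling((w[2] - rec$t0_s) * rec$rate_hz)
      if (i0 < 1 || i1 > length(x) || i1 < i0) {
        stop("window outside recording: [", w[1], ", ", w[2], ")", call. = FALSE)
      }
      seq.int(i0, i1)
    }))
    x[idx]
  }
  s <- pool(signal_windows)
  n <- pool(noise_windows)
  p_sig <- mean((s - mean(s))^2)
  p_noise <- mean((n - mean(n))^2)
  if (p_noise <= 0) stop("noise power is zero", call. = FALSE)
  10 * log10(p_sig / p_noise)
}
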