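# Fluorescence (calcium indicator) trace analysis: asymmetric least squares
# (ALS) baseline estimation, delta-F/F, reference-ROI subtraction,
# event-aligned averaging, and recovery-time estimation for the
# electrode-insertion damage assay.

#' Construct a fluorescence ROI trace
#'
#' Mean ROI gray values over time, uniformly sampled (1% tolerance on the
#' sampling interval).
#'
#' @param t_s increasing sample times (seconds).
#' @param f nonnegative finite fluorescence values (arbitrary units).
#' @return object of class `fluorescence_trace` with fields `t_s`, `f`,
#'   `rate_hz`.
#' @export
fluorescence_trace <- function(t_s, f) {
  t_s <- as.numeric(t_s)
  f <- as.numeric(f)
  if (length(t_s) != length(f)) stop("t_s and f lengths differ", call. = FALSE)
  if (length(t_s) < 2) stop("need at least 2 samples", call. = FALSE)
  if (any(!is.finite(f))) stop("non-finite fluorescence values", call. = FALSE)
  dt <- diff(t_s)
  if (any(dt <= 0)) stop("t_s must be increasing", call. = FALSE)
  dt0 <- stats::median(dt)
  if (any(abs(dt - dt0) > 0.01 * dt0)) {
    stop("sampling non-uniform beyond 1% tolerance", call. = FALSE)
  }
  structure(list(t_s = t_s, f = f, rate_hz = 1 / dt0),
            class = "fluorescence_trace")
}

#' Read a fluorescence ROI trace from CSV
#'
#' Expects columns `time_s` (or `time`) and one value column (the first
#' non-time column is used).
#'
#' @param path CSV file.
#' @return a [fluorescence_trace()].
#' @export
read_fluorescence <- function(path) {
  df <- utils::read.csv(path)
  time_col <- intersect(c("time_s", "time"), names(df))[1]
  if (is.na(time_col)) stop("no time column in ", path, call. = FALSE)
  val_col <- setdiff(names(df), time_col)[1]
  fluorescence_trace(df[[time_col]], df[[val_col]])
}

#' Asymmetric least squares (ALS) baseline
#'
#' Iteratively reweighted penalized least squares: minimizes
#' `sum(w_i * (f_i - z_i)^2) + lam * sum(diff(z, differences = 2)^2)` where
#' `w_i = p` for points above the current baseline and `1 - p` below. With
#' small `p` the baseline hugs the lower envelope under positive transients
#' while the second-difference penalty keeps it smooth. `lam` sets the
#' stiffness and must grow roughly with the fourth power of the transient
#' width (in samples) that the baseline should ignore.
#'
#' @param trace a [fluorescence_trace()] or numeric vector.
#' @param lam smoothness penalty (default `1e5`).
#' @param p asymmetry weight in `(0, 1)` (default 0.01).
#' @param n_iter reweighting iterations (default 10).
#' @return numeric baseline vector (same length as the input).
#' @export
als_baseline <- function(trace, lam = 1e5, p = 0.01, n_iter = 10) {
  f <- if (inherits(trace, "fluorescence_trace")) trace$f else as.numeric(trace)
  n <- length(f)
  if (n < 10) stop("need at least 10 samples", call. = FALSE)
  if (any(!is.finite(f))) stop("non-finite input", call. = FALSE)
  if (p <= 0 || p >= 1) stop("p must be in (0, 1)", call. = FALSE)
  d2 <- Matrix::bandSparse(n - 2, n, k = 0:2,
                           diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                            rep(1, n - 2)))
  penalty <- lam * Matrix::crossprod(d2)
  w <- rep(1, n)
  z <- f
  for (it in seq_len(n_iter)) {
    lhs <- penalty + Matrix::Diagonal(n, w)
    z <- as.numeric(Matrix::solve(lhs, w * f))
    w <- ifelse(f > z, p, 1 - p)
  }
  z
}

#' Delta-F/F trace
#'
#' `(F(t) - F0) / F0` elementwise, where `F0` is the baseline (e.g. from
#' [als_baseline()]).
#'
#' @param trace a [fluorescence_trace()].
#' @param baseline positive baseline vector (recycled if scalar).
#' @return object of class `dff_trace` with fields `t_s`, `dff`, `f0`,
#'   `rate_hz`.
#' @export
dff <- function(trace, baseline) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  f0 <- rep_len(as.numeric(baseline), length(trace$f))
  if (any(f0 <= 0)) stop("baseline must be positive everywhere", call. = FALSE)
  structure(list(t_s = trace$t_s, dff = (trace$f - f0) / f0, f0 = f0,
                 rate_hz = trace$rate_hz),
            class = "dff_trace")
}

new_dff_trace <- function(t_s, dff_values, f0, rate_hz) {
  structure(list(t_s = t_s, dff = dff_values, f0 = f0, rate_hz = rate_hz),
            class = "dff_trace")
}

#' Subtract a reference-ROI delta-F/F trace
#'
#' Removes culture-wide spontaneous activity by subtracting the delta-F/F of
#' an unaffected reference region from the affected region, pointwise. The
#' reference is linearly resampled onto the affected timebase when the rates
#' differ by more than 1%; non-overlapping timebases are an error.
#'
#' @param affected,reference `dff_trace` objects.
#' @return a `dff_trace` on the affected timebase.
#' @export
roi_subtract <- function(affected, reference) {
  stopifnot(inherits(affected, "dff_trace"), inherits(reference, "dff_trace"))
  if (abs(affected$rate_hz - reference$rate_hz) > 0.01 * affected$rate_hz ||
      length(affected$t_s) != length(reference$t_s) ||
      max(abs(affected$t_s - reference$t_s)) > 0.5 / affected$rate_hz) {
    if (max(reference$t_s) < min(affected$t_s) ||
        min(reference$t_s) > max(affected$t_s)) {
      stop("timebases do not overlap", call. = FALSE)
    }
    ref <- stats::approx(reference$t_s, reference$dff, xout = affected$t_s,
                         rule = 1)$y
    if (any(is.na(ref))) stop("reference does not cover the affected timebase",
                              call. = FALSE)
  } else {
    ref <- reference$dff
  }
  new_dff_trace(affected$t_s, affected$dff - ref, affected$f0,
                affected$rate_hz)
}

#' Event-aligned average of delta-F/F traces
#'
#' Shifts each trace so its event time is zero, truncates to the common time
#' support, and returns the pointwise mean and standard deviation.
#'
#' @param traces list of `dff_trace` objects (at least 2).
#' @param event_times_s one event time per trace, inside its timebase.
#' @return list with `t_s` (time relative to the event), `mean`, and `sd`.
#' @export
align_average <- function(traces, event_times_s) {
  if (length(traces) < 2) stop("need at least 2 traces", call. = FALSE)
  if (length(event_times_s) != length(traces)) {
    stop("one event time per trace required", call. = FALSE)
  }
  rel <- Map(function(tr, ev) {
    if (ev < min(tr$t_s) || ev > max(tr$t_s)) {
      stop("event time outside trace", call. = FALSE)
    }
    list(t = tr$t_s - ev, dff = tr$dff, rate = tr$rate_hz)
  }, traces, event_times_s)
  lo <- max(vapply(rel, function(r) min(r$t), numeric(1)))
  hi <- min(vapply(rel, function(r) max(r$t), numeric(1)))
  if (hi <= lo) stop("no common time support after alignment", call. = FALSE)
  rate <- rel[[1]]$rate
  grid <- seq(lo, hi, by = 1 / rate)
  mat <- vapply(rel, function(r) stats::approx(r$t, r$dff, xout = grid)$y,
                numeric(length(grid)))
  list(t_s = grid, mean = rowMeans(mat), sd = apply(mat, 1, stats::sd))
}

#' Recovery time after a transient event
#'
#' Finds the post-event peak of `|dff|` and returns the elapsed time from the
#' event to the first instant after the peak at which `|dff|` stays at or
#' below `frac` for `sustain_s` consecutive seconds (the sustain requirement
#' suppresses spurious noise crossings). "Within `frac` of baseline" is read
#' on the delta-F/F scale: `|dff| <= frac`.
#'
#' @param trace a `dff_trace`.
#' @param event_s event time (seconds), inside the trace.
#' @param frac recovery band on the delta-F/F scale (default 0.02).
#' @param sustain_s time the signal must stay inside the band (default 60 s).
#' @return recovery time in seconds since `event_s`, or `NA` if the signal
#'   never recovers within the trace.
#' @export
recovery_time <- function(trace, event_s, frac = 0.02, sustain_s = 60) {
  stopifnot(inherits(trace, "dff_trace"))
  post <- which(trace$t_s >= event_s)
  if (!length(post)) stop("no post-event data", call. = FALSE)
  a <- abs(trace$dff[post])
  peak_i <- which.max(a)
  if (a[peak_i] <= frac) {
    stop("no post-event peak above the recovery band", call. = FALSE)
  }
  below <- a <= frac
  n_sustain <- max(1L, ceiling(sustain_s * trace$rate_hz))
  i <- peak_i
  n <- length(a)
  while (i <= n) {
    if (below[i]) {
      j_end <- min(n, i + n_sustain - 1L)
      if (all(below[i:j_end])) {
        return(trace$t_s[post[i]] - event_s)
      }
      i <- i + which(!below[i:j_end])[1]
    } else {
      i <- i + 1L
    }
  }
  NA_real_
}
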