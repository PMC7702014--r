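# Recording and event-table I/O. CSV is the primary interchange format;
# EDF (European Data Format, 16-bit) is supported for interoperability with
# electrophysiology tooling. Amplitudes are volts in memory; declared input
# units are converted at this boundary.

.unit_scale <- function(unit) {
  switch(tolower(unit),
         "v" = 1, "volt" = 1, "volts" = 1,
         "mv" = 1e-3,
         "uv" = , "µv" = 1e-6,
         stop("unknown amplitude unit: ", unit, call. = FALSE))
}

.guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "edf") "edf" else if (ext %in% c("csv", "tsv", "txt")) "csv"
  else stop("cannot infer recording format from extension: ", path,
            call. = FALSE)
}

#' Read an LFP recording from EDF or CSV
#'
#' CSV files must have a header row; a `time_s` (or `time`) column gives the
#' time axis, all other columns are channels. Alternatively a file without a
#' time column is accepted when `rate_hz` is supplied. Timestamps must be
#' uniform to within 1 ppm of the sampling interval.
#'
#' @param path input file.
#' @param format `"edf"`, `"csv"`, or `"auto"` (by extension).
#' @param unit amplitude unit of the stored values (`"V"`, `"mV"`, `"uV"`);
#'   converted to volts. Ignored for EDF, whose header declares the unit.
#' @param rate_hz sampling rate, required for CSV files without a time column.
#' @return an [recording()] object (amplitudes in volts).
#' @export
read_recording <- function(path, format = c("auto", "edf", "csv"), unit = "V",
                           rate_hz = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") format <- .guess_format(path)
  if (format == "edf") return(read_edf(path))
  df <- utils::read.csv(path, check.names = FALSE)
  if (!nrow(df)) stop("empty recording file: ", path, call. = FALSE)
  time_col <- intersect(c("time_s", "time"), names(df))[1]
  if (!is.na(time_col)) {
    t <- df[[time_col]]
    df[[time_col]] <- NULL
    if (length(t) < 2) stop("need at least 2 samples", call. = FALSE)
    dt <- diff(t)
    dt0 <- median(dt)
    if (any(abs(dt - dt0) > 1e-6 * dt0 + 1e-12)) {
      stop("non-uniform timestamps (beyond 1 ppm tolerance)", call. = FALSE)
    }
    rate_hz <- 1 / dt0
    t0 <- t[1]
  } else {
    if (is.null(rate_hz)) {
      stop("CSV has no time column; supply rate_hz", call. = FALSE)
    }
    t0 <- 0
  }
  if (!ncol(df)) stop("no channel columns in ", path, call. = FALSE)
  scale <- .unit_scale(unit)
  recording(t(as.matrix(df)) * scale, rate_hz = rate_hz, t0_s = t0,
            channel_ids = names(df))
}

#' Write an LFP recording to EDF or CSV
#'
#' CSV output has a `time_s` column followed by one column per channel, in
#' volts. EDF stores 16-bit samples scaled to the per-channel amplitude range
#' (physical unit mV).
#'
#' @param rec an [recording()] object.
#' @param path output file.
#' @param format `"edf"`, `"csv"`, or `"auto"` (by extension).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "edf", "csv")) {
  stopifnot(inherits(rec, "lfp_recording"))
  format <- match.arg(format)
  if (format == "auto") format <- .guess_format(path)
  if (nrow(rec$samples) == 0) stop("recording has no channels", call. = FALSE)
  if (format == "edf") return(write_edf(rec, path))
  df <- data.frame(time_s = time_axis(rec))
  for (i in seq_len(nrow(rec$samples))) df[[rec$channel_ids[i]]] <- rec$samples[i, ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# ---- EDF ---------------------------------------------------------------------
# Minimal EDF implementation: one data record holding the full signal,
# physical unit mV, digital range -32768..32767. Sufficient for lossless-to-
# quantisation round trips of continuous recordings.

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

.edf_num <- function(x, width) {
  s <- formatC(signif(x, width - 2), width = 1, digits = width - 2,
               format = "g")
  if (nchar(s) > width) s <- substr(s, 1, width)
  .edf_pad(s, width)
}

write_edf <- function(rec, path) {
  ns <- nrow(rec$samples)
  npts <- ncol(rec$samples)
  mv <- rec$samples * 1e3  # physical values in mV
  pmin <- apply(mv, 1, min)
  pmax <- apply(mv, 1, max)
  flat <- pmax - pmin < 1e-12
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8), .edf_pad("X", 80), .edf_pad("X", 80),
    .edf_pad("01.01.00", 8), .edf_pad("00.00.00", 8),
    .edf_pad(256 + 256 * ns, 8), .edf_pad("", 44),
    .edf_pad(1, 8), .edf_num(npts / rec$rate_hz, 8), .edf_pad(ns, 4),
    paste(vapply(rec$channel_ids, .edf_pad, "", width = 16), collapse = ""),
    paste(rep(.edf_pad("", 80), ns), collapse = ""),
    paste(rep(.edf_pad("mV", 8), ns), collapse = ""),
    paste(vapply(pmin, .edf_num, "", width = 8), collapse = ""),
    paste(vapply(pmax, .edf_num, "", width = 8), collapse = ""),
    paste(rep(.edf_pad(-32768, 8), ns), collapse = ""),
    paste(rep(.edf_pad(32767, 8), ns), collapse = ""),
    paste(rep(.edf_pad("", 80), ns), collapse = ""),
    paste(rep(.edf_pad(npts, 8), ns), collapse = ""),
    paste(rep(.edf_pad("", 32), ns), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)
  # re-read the header's rounded physical range so scaling is self-consistent
  pmin_r <- as.numeric(vapply(pmin, .edf_num, "", width = 8))
  pmax_r <- as.numeric(vapply(pmax, .edf_num, "", width = 8))
  for (i in seq_len(ns)) {
    dig <- round((mv[i, ] - pmin_r[i]) / (pmax_r[i] - pmin_r[i]) * 65535 - 32768)
    dig <- pmin(pmax(dig, -32768), 32767)
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- rd(8)
  if (version != "0") stop("not an EDF file: ", path, call. = FALSE)
  rd(80); rd(80); rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  vapply(seq_len(ns), function(i) rd(80), "")
  units <- vapply(seq_len(ns), function(i) rd(8), "")
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(80), "")
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(32), "")
  chans <- vector("list", ns)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2, endian = "little")
      phys <- pmin[i] + (dig - dmin[i]) / (dmax[i] - dmin[i]) * (pmax[i] - pmin[i])
      chans[[i]] <- c(chans[[i]], phys)
    }
  }
  scale <- vapply(units, function(u) {
    if (u == "") 1 else .unit_scale(u)
  }, numeric(1))
  samples <- do.call(rbind, lapply(seq_len(ns), function(i) chans[[i]] * scale[i]))
  rate <- spr[1] / rec_dur
  recording(samples, rate_hz = rate, channel_ids = labels)
}

# ---- Event tables ------------------------------------------------------------

#' Write / read an event table as CSV
#'
#' Columns: `channel_id,start_s,end_s,kind,value`. Rows are written sorted by
#' `(channel_id, start_s)`; the round trip is lossless.
#'
#' @param tbl an [event_table()].
#' @param path CSV file path.
#' @return `write_events()`: `path` invisibly; `read_events()`: an
#'   `event_table`.
#' @export
write_events <- function(tbl, path) {
  tbl <- validate_event_table(as.data.frame(tbl))
  utils::write.csv(tbl, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(channel_id = "character"))
  for (col in c("start_s", "end_s", "value")) {
    if (col %in% names(df)) {
      v <- df[[col]]
      if (is.character(v)) v[v == ""] <- NA
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(!is.na(v) & is.na(vn))
      if (length(bad)) {
        stop("malformed numeric value in column '", col, "' at row ", bad[1],
             call. = FALSE)
      }
      df[[col]] <- vn
    }
  }
  if (!nrow(df)) {
    return(event_table())
  }
  validate_event_table(df)
}
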