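# The jitter statistic: the mean normalized absolute difference between
# matched inter-spike intervals of two seizures, in percent. Seizures are
# aligned at one spike from each train; intervals are paired by their signed
# offset from the alignment spike, and the alignment minimizing the jitter is
# chosen automatically.

#' Inter-spike intervals of a train
#'
#' @param train a [spike_train()] with at least 2 spikes.
#' @return successive differences of the spike times (seconds), all positive;
#'   length `n_spikes - 1`.
#' @export
spike_intervals <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  if (length(train$times_s) < 2) {
    stop("need at least 2 spikes to form intervals", call. = FALSE)
  }
  diff(train$times_s)
}

# Jitter for a fixed alignment shift d = ib - ia over the interval vectors.
# Interval k of train a (between spikes k and k+1) is paired with interval
# k + d of train b; the mean of 100 * |Ia - Ib| / ((Ia + Ib) / 2) is taken
# over the overlapping range.
.jitter_shift <- function(ia_int, ib_int, d) {
  ka <- max(1L, 1L - d)
  kb <- min(length(ia_int), length(ib_int) - d)
  if (kb < ka) return(list(jitter_pct = NA_real_, n_interval = 0L))
  a <- ia_int[ka:kb]
  b <- ib_int[(ka + d):(kb + d)]
  list(jitter_pct = 100 * mean(abs(a - b) / ((a + b) / 2)),
       n_interval = kb - ka + 1L)
}

#' Jitter between two trains at a fixed alignment
#'
#' Both trains are anchored at their alignment spikes (`ia`, `ib`, 1-based);
#' each interval is indexed by its signed offset from the anchor and intervals
#' sharing an offset present in both trains are paired. The jitter is
#' `100 * mean(|Ia - Ib| / ((Ia + Ib) / 2))` over the paired intervals.
#'
#' @param a,b [spike_train()] objects with at least 2 spikes each.
#' @param ia,ib alignment spike indices (1-based).
#' @return list with `jitter_pct` and `n_interval` (number of paired
#'   intervals).
#' @export
jitter_at_alignment <- function(a, b, ia, ib) {
  int_a <- spike_intervals(a)
  int_b <- spike_intervals(b)
  if (ia < 1 || ia > length(a$times_s) || ib < 1 || ib > length(b$times_s)) {
    stop("alignment index out of range", call. = FALSE)
  }
  res <- .jitter_shift(int_a, int_b, as.integer(ib) - as.integer(ia))
  if (res$n_interval == 0) {
    stop("alignment pairs no intervals", call. = FALSE)
  }
  res
}

#' Optimal-alignment jitter between two seizure spike trains
#'
#' Evaluates the fixed-alignment jitter over all alignment spike pairs and
#' returns the minimum. Ties are broken by the lexicographically smallest
#' `(ia, ib)`. Because the paired-interval set depends on the alignments only
#' through the shift `ib - ia`, the search runs over the
#' `n_a + n_b - 1` distinct shifts.
#'
#' @param a,b [spike_train()] objects (or [seizure()] objects, whose trains
#'   are used) with at least 2 spikes each.
#' @return list of class `jitter_result`: `jitter_pct`, alignment indices
#'   `align_idx_1` and `align_idx_2` (1-based), and `n_interval`.
#' @export
jitter <- function(a, b) {
  if (inherits(a, "seizure")) a <- a$spikes
  if (inherits(b, "seizure")) b <- b$spikes
  int_a <- spike_intervals(a)
  int_b <- spike_intervals(b)
  na <- length(a$times_s)
  nb <- length(b$times_s)
  best <- NULL
  # enumerate shifts in the order of their lexicographically smallest
  # realizing (ia, ib) pair: d >= 0 realized by (1, 1 + d) comes first
  # (increasing d), then d < 0 realized by (1 - d, 1) (decreasing d).
  shifts <- c(0:(nb - 1), -(1:(na - 1)))
  for (d in shifts) {
    res <- .jitter_shift(int_a, int_b, d)
    if (res$n_interval == 0) next
    if (is.null(best) || res$jitter_pct < best$jitter_pct - 1e-12) {
      ia <- max(1L, 1L - d)
      best <- list(jitter_pct = res$jitter_pct, align_idx_1 = ia,
                   align_idx_2 = ia + d, n_interval = res$n_interval)
    }
  }
  structure(best, class = "jitter_result")
}

#' @export
print.jitter_result <- function(x, ...) {
  cat(sprintf("<jitter_result> %.3f%% (align %d ~ %d, %d paired intervals)\n",
              x$jitter_pct, x$align_idx_1, x$align_idx_2, x$n_interval))
  invisible(x)
}

#' Pairwise optimal-alignment jitter matrix
#'
#' @param seizures list of [seizure()] (or [spike_train()]) objects, at least
#'   two.
#' @return symmetric numeric matrix of jitter percentages with zero diagonal;
#'   rows/columns for seizures with fewer than 2 spikes are `NA`.
#' @export
pairwise_jitter <- function(seizures) {
  n <- length(seizures)
  if (n < 2) stop("need at least 2 seizures", call. = FALSE)
  trains <- lapply(seizures, function(s) if (inherits(s, "seizure")) s$spikes else s)
  usable <- vapply(trains, function(tr) length(tr$times_s) >= 2, logical(1))
  m <- matrix(NA_real_, n, n)
  diag(m) <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (usable[i] && usable[j]) {
        m[i, j] <- m[j, i] <- jitter(trains[[i]], trains[[j]])$jitter_pct
      }
    }
  }
  diag(m)[!usable] <- NA_real_
  m
}
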