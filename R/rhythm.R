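# Burst detection, cycle-frequency estimation and antagonist alternation
# analysis for slow motoneuron rhythms.

#' Detect bursts in a spike train
#'
#' A burst is a maximal run of spikes whose inter-spike intervals are all
#' at most `max_isi`, containing at least `min_spikes` spikes. Burst onset
#' and offset are the first and last spike of the run. The defaults
#' (`max_isi` 0.2 s, `min_spikes` 3) separate the 0.27-1.16 Hz burst
#' regimes of the slow rhythm from tonic activity.
#'
#' @param spikes Spike times (an [event_series()] or sorted numeric
#'   vector).
#' @param max_isi Maximum within-burst inter-spike interval (s).
#' @param min_spikes Minimum spikes per burst.
#' @return A data frame of class `burst_train` with columns `onset`,
#'   `offset`, `n_spikes`; possibly empty.
#' @export
detect_bursts <- function(spikes, max_isi = 0.2, min_spikes = 3) {
  sp <- as_event_times(spikes, "spike")
  empty <- data.frame(onset = numeric(), offset = numeric(),
                      n_spikes = integer())
  class(empty) <- c("burst_train", "data.frame")
  if (!length(sp)) return(empty)
  brk <- c(0L, which(diff(sp) > max_isi), length(sp))
  rows <- lapply(seq_len(length(brk) - 1L), function(i) {
    seg <- sp[(brk[i] + 1L):brk[i + 1L]]
    if (length(seg) < min_spikes) return(NULL)
    data.frame(onset = seg[1L], offset = seg[length(seg)],
               n_spikes = length(seg))
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  class(out) <- c("burst_train", "data.frame")
  out
}

#' Cycle frequency of a burst rhythm
#'
#' The inverse of the mean inter-onset interval of the bursts whose onsets
#' fall inside `interval`. Robust at small cycle counts, unlike a spectral
#' peak.
#'
#' @param bursts A `burst_train` (see [detect_bursts()]).
#' @param interval Optional `c(start, end)` window in seconds; default is
#'   the whole train.
#' @return Frequency in Hz, or `NA` (with a warning) when fewer than two
#'   onsets fall inside the interval.
#' @export
rhythm_frequency <- function(bursts, interval = NULL) {
  stopifnot(inherits(bursts, "burst_train"))
  on <- bursts$onset
  if (!is.null(interval)) {
    stopifnot(length(interval) == 2L, interval[1L] < interval[2L])
    on <- on[on >= interval[1L] & on <= interval[2L]]
  }
  if (length(on) < 2L) {
    warning("fewer than two burst onsets in the interval; frequency undefined")
    return(NA_real_)
  }
  1 / mean(diff(on))
}

#' Compare quiescent and stepping rhythm frequencies
#'
#' Paired t-test across animals by default (each animal contributes one
#' quiescent and one stepping frequency); Welch's t-test when unpaired.
#' Identical groups yield the degenerate result t = 0, p = 1.
#'
#' @param quiet,stepping Numeric vectors of cycle frequencies (Hz).
#' @param paired Use the paired per-animal design (default `TRUE`).
#' @return A list of class `freq_test`: `statistic`, `df`, `p`, `method`.
#' @export
compare_frequencies <- function(quiet, stepping, paired = TRUE) {
  quiet <- as.numeric(quiet); stepping <- as.numeric(stepping)
  if (length(quiet) < 2L || length(stepping) < 2L)
    stop("each group needs at least 2 values")
  if (paired && length(quiet) != length(stepping))
    stop("paired comparison needs equal-length groups")
  degenerate <- if (paired) stats::sd(stepping - quiet) == 0 else
    (stats::sd(quiet) == 0 && stats::sd(stepping) == 0)
  if (degenerate) {
    equal <- isTRUE(all.equal(mean(quiet), mean(stepping)))
    return(structure(list(statistic = if (equal) 0 else Inf, df = NA_real_,
                          p = if (equal) 1 else 0,
                          method = if (paired) "paired t" else "welch"),
                     class = "freq_test"))
  }
  ht <- if (paired) stats::t.test(stepping, quiet, paired = TRUE)
  else stats::t.test(stepping, quiet, var.equal = FALSE)
  structure(list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p = ht$p.value,
                 method = if (paired) "paired t" else "welch"),
            class = "freq_test")
}

#' @export
print.freq_test <- function(x, ...) {
  cat(sprintf("%s test: statistic %.4g, df %.3g, p = %.4g\n",
              x$method, x$statistic, x$df, x$p))
  invisible(x)
}

#' Lag-wise normalized cross-correlation of two envelopes
#'
#' Pearson correlation of the overlapping segments at each lag, over a
#' symmetric lag grid about 0, so antagonist alternation shows as a dip at
#' lag 0 with peaks near half the cycle period regardless of signal scale.
#' `r(lag)` correlates `A(t)` with `B(t + lag)`; swapping the inputs
#' negates the lag axis.
#'
#' @param envA,envB Aligned [sampled_trace()]s.
#' @param max_lag Maximum lag in seconds (< trace duration).
#' @return A data frame of class `lag_correlation` with columns `lag`
#'   (seconds) and `r` (in \[-1, 1\]).
#' @export
cross_correlate <- function(envA, envB, max_lag) {
  check_aligned(envA, envB)
  x <- envA$values; y <- envB$values
  n <- length(x)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("cross-correlation undefined for zero-variance input")
  L <- floor(max_lag * envA$fs)
  if (L < 1L || n - L < 3L)
    stop("`max_lag` must leave at least 3 overlapping samples")
  lags <- (-L):L
  r <- vapply(lags, function(k) {
    if (k >= 0L) stats::cor(x[1L:(n - k)], y[(1L + k):n])
    else stats::cor(x[(1L - k):n], y[1L:(n + k)])
  }, 0)
  out <- data.frame(lag = lags / envA$fs, r = r)
  class(out) <- c("lag_correlation", "data.frame")
  out
}

#' Bin a spike train into a smoothed rate envelope
#'
#' Utility for correlating spike trains: counts spikes in fixed bins and
#' boxcar-smooths the resulting rate trace.
#'
#' @param spikes Spike times.
#' @param t0,t1 Trace span in seconds.
#' @param fs Output sampling rate (Hz).
#' @param smooth_T Boxcar half-window (s); 0 disables smoothing.
#' @return A [sampled_trace()] of firing rate (spikes/s).
#' @export
spikes_to_rate <- function(spikes, t0, t1, fs = 50, smooth_T = 0.1) {
  sp <- as_event_times(spikes, "spike")
  edges <- seq(t0, t1, by = 1 / fs)
  counts <- tabulate(findInterval(sp[sp >= t0 & sp < t1], edges),
                     nbins = length(edges) - 1L)
  tr <- sampled_trace(counts * fs, fs = fs, t0 = t0 + 0.5 / fs,
                      label = "rate", units = "spikes/s")
  if (smooth_T > 0) tr <- smooth_boxcar(tr, smooth_T)
  tr
}
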