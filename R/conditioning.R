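# Trace-level preprocessing: rectification, boxcar and Gaussian smoothing,
# per-step normalization, antagonist crosstalk subtraction, and event
# detection from contact and spike signals.

#' Full-wave rectification
#'
#' @param trace A [sampled_trace()].
#' @return The trace with values replaced by their absolute value; metadata
#'   preserved. Idempotent.
#' @export
rectify <- function(trace) {
  stopifnot(inherits(trace, "sampled_trace"))
  trace$values <- abs(trace$values)
  trace
}

# internal: centred kernel smoothing with truncated, renormalized edge
# windows (no padding), so constant traces are fixed points
smooth_kernel <- function(x, k) {
  n <- length(x); m <- length(k); half <- (m - 1L) %/% 2L
  if (m == 1L) return(x * k / k)
  xp <- c(rep(0, half), x, rep(0, half))
  wp <- c(rep(0, half), rep(1, n), rep(0, half))
  num <- stats::filter(xp, k, method = "convolution", sides = 2)
  den <- stats::filter(wp, k, method = "convolution", sides = 2)
  idx <- (half + 1L):(half + n)
  as.numeric(num[idx] / den[idx])
}

#' Boxcar (moving-average) smoothing
#'
#' Centred moving average over the window \[t - T, t + T\]; at the edges the
#' window is truncated to the available samples and renormalized by the
#' actual sample count, so constant traces are unchanged everywhere.
#'
#' @param trace A [sampled_trace()].
#' @param T Half-window in seconds (>= 0); the default 0.05 s reproduces the
#'   standard EMG smoothing time constant. `T = 0` is the identity.
#' @return The smoothed [sampled_trace()].
#' @export
smooth_boxcar <- function(trace, T = 0.05) {
  stopifnot(inherits(trace, "sampled_trace"))
  if (!is.numeric(T) || length(T) != 1L || T < 0) stop("`T` must be >= 0")
  w <- round(T * trace$fs)
  if (w < 1) return(trace)
  k <- rep(1 / (2 * w + 1), 2 * w + 1)
  trace$values <- smooth_kernel(trace$values, k)
  trace
}

#' Gaussian smoothing (running Gaussian average)
#'
#' Convolution with a truncated, renormalized Gaussian kernel. `width` is
#' the total kernel support: the kernel is truncated at +/- `width`/2 and
#' its standard deviation is `width`/4. Edges use truncated renormalized
#' windows as in [smooth_boxcar()].
#'
#' @param trace A [sampled_trace()].
#' @param width Total kernel support in seconds (> 0); default 0.1 s
#'   (the 100 ms running Gaussian average used for retractor envelopes).
#' @return The smoothed [sampled_trace()].
#' @export
smooth_gaussian <- function(trace, width = 0.1) {
  stopifnot(inherits(trace, "sampled_trace"))
  if (!is.numeric(width) || length(width) != 1L || width <= 0)
    stop("`width` must be > 0")
  half <- floor(width / 2 * trace$fs)
  if (half < 1) return(trace)
  k <- stats::dnorm((-half:half) / trace$fs, sd = width / 4)
  k <- k / sum(k)
  trace$values <- smooth_kernel(trace$values, k)
  trace
}

#' Subtract antagonist crosstalk from an EMG envelope
#'
#' Both inputs should already be rectified and smoothed. The agonist is
#' min-max normalized to \[0, 1\]; the antagonist is rescaled so its minimum
#' is 0 and its maximum is `cap` (default 0.5, reflecting the smaller size
#' of the antagonist signal in the agonist channel) and subtracted
#' pointwise; negative results are clipped to 0. A constant antagonist
#' rescales to all-zero and leaves the agonist unchanged.
#'
#' @param agonist,antagonist Aligned [sampled_trace()]s (same fs, t0, length).
#' @param cap Upper bound of the rescaled antagonist.
#' @return The corrected agonist envelope as a [sampled_trace()] in \[0, 1\].
#' @export
remove_crosstalk <- function(agonist, antagonist, cap = 0.5) {
  check_aligned(agonist, antagonist)
  if (!is.numeric(cap) || length(cap) != 1L || cap < 0) stop("`cap` must be >= 0")
  minmax <- function(v) {
    r <- range(v)
    if (r[2L] - r[1L] <= 0) rep(0, length(v)) else (v - r[1L]) / (r[2L] - r[1L])
  }
  out <- pmax(minmax(agonist$values) - cap * minmax(antagonist$values), 0)
  agonist$values <- out
  agonist
}

#' Per-step min-max normalization
#'
#' Extracts the samples of one stance-anchored step cycle and affinely maps
#' them so the minimum activity is 0 and the maximum 1. A constant segment
#' maps to all zeros.
#'
#' @param trace A [sampled_trace()].
#' @param step A single step cycle: one row of a [segment_steps()] result or
#'   a list with `touchdown` and `next_touchdown`.
#' @return A [sampled_trace()] covering `[touchdown, next_touchdown)`.
#' @export
normalize_per_step <- function(trace, step) {
  stopifnot(inherits(trace, "sampled_trace"))
  td <- step$touchdown[1L]; nt <- step$next_touchdown[1L]
  if (is.null(td) || is.null(nt) || !is.finite(td) || !is.finite(nt) || nt <= td)
    stop("`step` must supply touchdown < next_touchdown")
  tt <- trace_times(trace)
  idx <- which(tt >= td - 1e-12 & tt < nt - 1e-12)
  if (!length(idx)) stop("step interval contains no samples of the trace")
  if (tt[idx[1L]] < trace$t0 - 1e-12 || td < trace$t0 - 1e-9 ||
      nt > tt[length(tt)] + 1 / trace$fs + 1e-9)
    stop("step interval lies outside the trace span")
  v <- trace$values[idx]
  r <- range(v)
  v <- if (r[2L] - r[1L] <= 0) rep(0, length(v)) else (v - r[1L]) / (r[2L] - r[1L])
  sampled_trace(v, fs = trace$fs, t0 = tt[idx[1L]], label = trace$label,
                units = "normalized")
}

#' Detect touchdown and lift-off events from a tarsal-contact trace
#'
#' The contact signal is high during swing and low during stance. A
#' touchdown is the downward crossing of `td_threshold` (sub-sample timing
#' by linear interpolation); the subsequent lift-off is the time of the
#' steepest ascending slope (maximum first difference) between that
#' touchdown and the next touchdown, with ties resolved to the earliest
#' sample. Alternation (touchdown, lift-off, touchdown, ...) is enforced by
#' construction.
#'
#' @param contact A [sampled_trace()].
#' @param td_threshold Threshold amplitude for the contact-onset crossing.
#' @return An [event_series()] of alternating `touchdown`/`liftoff` events;
#'   empty if the trace never crosses the threshold.
#' @export
detect_contact_events <- function(contact, td_threshold) {
  stopifnot(inherits(contact, "sampled_trace"))
  x <- contact$values
  n <- length(x)
  if (n < 2L) return(event_series())
  tt <- trace_times(contact)
  down <- which(x[-n] >= td_threshold & x[-1L] < td_threshold)
  if (!length(down)) return(event_series())
  td_times <- tt[down] + (x[down] - td_threshold) / (x[down] - x[down + 1L]) / contact$fs
  ev_t <- numeric(); ev_k <- character()
  for (j in seq_along(down)) {
    ev_t <- c(ev_t, td_times[j]); ev_k <- c(ev_k, "touchdown")
    lo_end <- if (j < length(down)) down[j + 1L] else n
    seg <- down[j]:(lo_end - 1L)
    if (length(seg) < 2L) next
    d <- x[seg + 1L] - x[seg]
    dmax <- max(d)
    if (dmax <= 0) next
    # earliest of (numerically) tied steepest slopes
    i <- seg[which(d >= dmax - 1e-9 * max(dmax, 1e-300))[1L]]
    ev_t <- c(ev_t, tt[i]); ev_k <- c(ev_k, "liftoff")
  }
  event_series(ev_t, ev_k, contact$label)
}

#' Detect spikes by threshold crossing
#'
#' One spike per supra-threshold excursion of a rectified trace,
#' timestamped at the excursion's (earliest) local maximum; excursions whose
#' gap is shorter than `dead_time` are merged into one.
#'
#' @param trace A rectified [sampled_trace()].
#' @param threshold Detection threshold (> 0).
#' @param dead_time Minimum separation between distinct excursions (s).
#' @return An [event_series()] of `spike` events.
#' @export
detect_spikes <- function(trace, threshold, dead_time = 0.001) {
  stopifnot(inherits(trace, "sampled_trace"))
  if (!is.numeric(threshold) || threshold <= 0) stop("`threshold` must be > 0")
  x <- trace$values
  above <- x > threshold
  if (!any(above)) return(event_series())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- c(1L, ends[-length(ends)] + 1L)
  runs <- cbind(starts[r$values], ends[r$values])
  gap_max <- dead_time * trace$fs
  merged <- list(runs[1L, ])
  if (nrow(runs) > 1L) for (i in 2L:nrow(runs)) {
    last <- merged[[length(merged)]]
    if (runs[i, 1L] - last[2L] - 1L < gap_max)
      merged[[length(merged)]] <- c(last[1L], runs[i, 2L])
    else merged[[length(merged) + 1L]] <- runs[i, ]
  }
  tt <- trace_times(trace)
  peaks <- vapply(merged, function(rn) {
    seg <- rn[1L]:rn[2L]
    tt[seg[which.max(x[seg])]]
  }, 0)
  event_series(peaks, "spike", trace$label)
}
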