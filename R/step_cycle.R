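# Stance-anchored step cycles: segmentation, period statistics, cycle
# phase, first-spike latencies, and step-triggered activity profiles.

#' Segment touchdown/lift-off events into stance-anchored step cycles
#'
#' Each cycle runs from one touchdown (stance onset) to the next; it pairs
#' a touchdown with the unique lift-off occurring before the next
#' touchdown. Leading lift-offs and the trailing unpaired touchdown are
#' dropped; a touchdown interval containing zero or more than one lift-off
#' is rejected (counted in the `n_rejected` attribute). Cycles whose period
#' exceeds the mean by more than `pause_sd` sample SDs are flagged as
#' pauses (`pause` column) and excluded from [period_stats()].
#'
#' @param touchdowns Touchdown times: an [event_series()] (which may also
#'   carry the lift-offs) or a sorted numeric vector.
#' @param liftoffs Lift-off times; omit if `touchdowns` is an
#'   [event_series()] containing both kinds.
#' @param leg,side Labels attached to every cycle (`"FL"`/`"ML"`,
#'   `"inside"`/`"outside"`).
#' @param pause_sd Pause-flag threshold in sample SDs above the mean period.
#' @return A data frame of class `step_cycles` with columns `leg`, `side`,
#'   `touchdown`, `liftoff`, `next_touchdown`, `period`, `stance`, `swing`,
#'   `pause`. `stance + swing == period` exactly.
#' @examples
#' st <- segment_steps(c(0, 1, 2), c(0.6, 1.6))
#' st$period
#' @export
segment_steps <- function(touchdowns, liftoffs = NULL, leg = "FL",
                          side = "inside", pause_sd = 5) {
  if (inherits(touchdowns, "event_series") && is.null(liftoffs)) {
    liftoffs <- events_of(touchdowns, "liftoff")
    touchdowns <- events_of(touchdowns, "touchdown")
  } else {
    touchdowns <- as_event_times(touchdowns, "touchdown")
    liftoffs <- as_event_times(liftoffs, "liftoff")
  }
  empty <- data.frame(leg = character(), side = character(),
                      touchdown = numeric(), liftoff = numeric(),
                      next_touchdown = numeric(), period = numeric(),
                      stance = numeric(), swing = numeric(),
                      pause = logical(), stringsAsFactors = FALSE)
  class(empty) <- c("step_cycles", "data.frame")
  if (length(touchdowns) < 2L) {
    attr(empty, "n_rejected") <- 0L
    return(empty)
  }
  td <- numeric(); lo <- numeric(); nt <- numeric()
  n_rejected <- 0L
  for (k in seq_len(length(touchdowns) - 1L)) {
    within <- liftoffs[liftoffs > touchdowns[k] & liftoffs < touchdowns[k + 1L]]
    if (length(within) != 1L) {
      n_rejected <- n_rejected + 1L
      next
    }
    td <- c(td, touchdowns[k]); lo <- c(lo, within)
    nt <- c(nt, touchdowns[k + 1L])
  }
  if (n_rejected > 0L)
    message("segment_steps: rejected ", n_rejected,
            " cycle(s) without a unique lift-off")
  res <- data.frame(leg = rep(leg, length(td)), side = rep(side, length(td)),
                    touchdown = td, liftoff = lo, next_touchdown = nt,
                    period = nt - td, stance = lo - td, swing = nt - lo,
                    stringsAsFactors = FALSE)
  res$pause <- if (nrow(res) >= 2L && stats::sd(res$period) > 0)
    res$period > mean(res$period) + pause_sd * stats::sd(res$period)
  else rep(FALSE, nrow(res))
  attr(res, "n_rejected") <- n_rejected
  class(res) <- c("step_cycles", "data.frame")
  res
}

#' Mean and SD of step periods
#'
#' @param steps A `step_cycles` data frame; pause-flagged cycles are
#'   excluded.
#' @return A list of class `period_summary`: `mean`, `sd`, `n` (seconds).
#' @export
period_stats <- function(steps) {
  stopifnot(inherits(steps, "step_cycles"))
  p <- steps$period[!steps$pause]
  if (!length(p)) stop("no (non-pause) step cycles to summarize")
  structure(list(mean = mean(p),
                 sd = if (length(p) > 1L) stats::sd(p) else 0,
                 n = length(p)),
            class = "period_summary")
}

#' @export
print.period_summary <- function(x, ...) {
  cat(sprintf("period: mean %.4g s, SD %.4g s, n = %d\n", x$mean, x$sd, x$n))
  invisible(x)
}

#' Compare step periods between two groups of sequences
#'
#' Two-sided test on per-sequence mean periods: Welch's t-test by default,
#' or a Wilcoxon rank-sum test via `method = "wilcox"`. When both groups
#' have zero variance and equal means the degenerate result t = 0, p = 1 is
#' returned.
#'
#' @param groupA,groupB Numeric vectors of per-sequence mean periods (or
#'   lists of [period_stats()] summaries).
#' @param method `"welch"` or `"wilcox"`.
#' @return A list of class `period_test`: `statistic`, `df`, `p`, `method`.
#' @export
compare_periods <- function(groupA, groupB, method = c("welch", "wilcox")) {
  method <- match.arg(method)
  to_num <- function(g) {
    if (is.list(g) && all(vapply(g, inherits, TRUE, "period_summary")))
      vapply(g, `[[`, 0, "mean")
    else as.numeric(g)
  }
  a <- to_num(groupA); b <- to_num(groupB)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 sequences")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    equal <- isTRUE(all.equal(mean(a), mean(b)))
    return(structure(list(statistic = if (equal) 0 else Inf,
                          df = NA_real_, p = if (equal) 1 else 0,
                          method = method), class = "period_test"))
  }
  if (method == "welch") {
    ht <- stats::t.test(a, b, var.equal = FALSE)
    structure(list(statistic = unname(ht$statistic), df = unname(ht$parameter),
                   p = ht$p.value, method = "welch"), class = "period_test")
  } else {
    ht <- stats::wilcox.test(a, b, exact = FALSE)
    structure(list(statistic = unname(ht$statistic), df = NA_real_,
                   p = ht$p.value, method = "wilcox"), class = "period_test")
  }
}

#' @export
print.period_test <- function(x, ...) {
  cat(sprintf("%s test: statistic %.4g, df %.3g, p = %.4g\n",
              x$method, x$statistic, x$df, x$p))
  invisible(x)
}

#' Step-cycle phase of time points
#'
#' The phase of the step cycle runs from the start of one stance phase to
#' the start of the next: `(t - touchdown) / period`, in \[0, 1). Times
#' falling outside every cycle get `NA`.
#'
#' @param t Numeric vector of times in seconds.
#' @param steps A `step_cycles` data frame (sorted by touchdown).
#' @return Numeric vector of cycle fractions in \[0, 1), `NA` where
#'   undefined.
#' @export
phase_at <- function(t, steps) {
  stopifnot(inherits(steps, "step_cycles"))
  out <- rep(NA_real_, length(t))
  if (!nrow(steps)) return(out)
  i <- findInterval(t, steps$touchdown)
  ok <- i >= 1L & i <= nrow(steps)
  ok[ok] <- t[ok] < steps$next_touchdown[i[ok]]
  out[ok] <- (t[ok] - steps$touchdown[i[ok]]) / steps$period[i[ok]]
  out
}

#' Normalized first-spike latency per step cycle
#'
#' For each cycle, the latency of the first spike at or after the anchor
#' event (touchdown or lift-off), normalized by that cycle's period. Only
#' spikes before the cycle's next touchdown count; cycles without one are
#' flagged missing.
#'
#' @param spikes Spike times: an [event_series()] or sorted numeric vector.
#' @param anchor `"touchdown"` or `"liftoff"`.
#' @param steps A `step_cycles` data frame.
#' @return A data frame with columns `cycle`, `latency` (cycle fraction,
#'   `NA` when missing).
#' @export
first_spike_latency <- function(spikes, anchor = c("touchdown", "liftoff"),
                                steps) {
  anchor <- match.arg(anchor)
  stopifnot(inherits(steps, "step_cycles"))
  sp <- as_event_times(spikes, "spike")
  lat <- vapply(seq_len(nrow(steps)), function(k) {
    a <- steps[[anchor]][k]
    s <- sp[sp >= a & sp < steps$next_touchdown[k]]
    if (!length(s)) NA_real_ else (s[1L] - a) / steps$period[k]
  }, 0)
  data.frame(cycle = seq_len(nrow(steps)), latency = lat)
}

#' Step-triggered average activity profile
#'
#' Each cycle's trace segment is min-max normalized
#' ([normalize_per_step()]), resampled by linear interpolation onto a fixed
#' grid of `n_bins` phase-bin centres, and averaged across cycles.
#'
#' @param trace A [sampled_trace()].
#' @param steps A `step_cycles` data frame; cycles outside the trace span
#'   are skipped (with a message).
#' @param n_bins Number of phase bins (>= 2).
#' @return A list of class `step_profile`: `phase` (bin centres), `mean`,
#'   `sd`, `n` (cycles used). Values lie in \[0, 1\].
#' @export
step_triggered_average <- function(trace, steps, n_bins = 20) {
  stopifnot(inherits(trace, "sampled_trace"), inherits(steps, "step_cycles"))
  if (!is.numeric(n_bins) || n_bins < 2) stop("`n_bins` must be >= 2")
  n_bins <- as.integer(n_bins)
  centres <- (seq_len(n_bins) - 0.5) / n_bins
  acc <- matrix(NA_real_, nrow = nrow(steps), ncol = n_bins)
  tt_end <- trace$t0 + (length(trace$values) - 1) / trace$fs
  skipped <- 0L
  for (k in seq_len(nrow(steps))) {
    if (steps$touchdown[k] < trace$t0 - 1e-9 ||
        steps$next_touchdown[k] > tt_end + 1e-9) {
      skipped <- skipped + 1L
      next
    }
    seg <- normalize_per_step(trace, steps[k, ])
    ph <- (trace_times(seg) - steps$touchdown[k]) / steps$period[k]
    if (length(seg$values) < 2L) { skipped <- skipped + 1L; next }
    acc[k, ] <- stats::approx(ph, seg$values, xout = centres, rule = 2,
                              ties = "ordered")$y
  }
  if (skipped > 0L)
    message("step_triggered_average: skipped ", skipped, " cycle(s)")
  used <- stats::complete.cases(acc)
  if (!any(used)) stop("no step cycle lies within the trace span")
  acc <- acc[used, , drop = FALSE]
  structure(list(phase = centres,
                 mean = colMeans(acc),
                 sd = apply(acc, 2L, stats::sd),
                 n = nrow(acc)),
            class = "step_profile")
}
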