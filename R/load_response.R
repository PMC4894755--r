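# Quantification and classification of motor responses to
# campaniform-sensilla load stimuli: peristimulus time histograms, the
# 150 ms normalized response magnitude, pre/post Michelson contrast, and
# three-way response classification.

#' Peristimulus time histogram
#'
#' Counts events in bins spanning `[-pre, +post)` around each stimulus,
#' summed over stimuli. Bin edges are aligned so that one edge falls at
#' lag 0; `pre` and `post` are covered up to whole bins.
#'
#' @param events Event times (an [event_series()] or numeric vector).
#' @param stim_times Stimulus onset times (an [event_series()] or numeric
#'   vector); must be non-empty.
#' @param pre,post Window extents before/after the stimulus (s, >= 0).
#' @param bin Bin width in seconds (> 0).
#' @return A data frame of class `psth` with columns `lag_lo`, `lag_hi`,
#'   `mid`, `count`, and attributes `n_stimuli` and `rate` (count /
#'   (n_stimuli * bin)).
#' @export
psth <- function(events, stim_times, pre = 0.5, post = 0.5, bin = 0.01) {
  ev <- as_event_times(events)
  st <- if (inherits(stim_times, "event_series"))
    as_event_times(stim_times, "stim_onset") else as_event_times(stim_times)
  if (!length(st)) stop("`stim_times` must contain at least one stimulus")
  if (!is.numeric(bin) || bin <= 0) stop("`bin` must be > 0")
  if (pre < 0 || post < 0) stop("`pre` and `post` must be >= 0")
  edges <- sort(unique(c(-rev(seq(0, pre, by = bin)), seq(0, post, by = bin))))
  nb <- length(edges) - 1L
  if (nb < 1L) stop("window shorter than one bin")
  counts <- integer(nb)
  for (s in st) {
    lag <- ev[ev >= s + edges[1L] & ev < s + edges[nb + 1L]] - s
    if (length(lag))
      counts <- counts + tabulate(findInterval(lag, edges), nbins = nb)
  }
  out <- data.frame(lag_lo = edges[-(nb + 1L)], lag_hi = edges[-1L],
                    mid = (edges[-(nb + 1L)] + edges[-1L]) / 2,
                    count = counts)
  attr(out, "n_stimuli") <- length(st)
  attr(out, "rate") <- counts / (length(st) * bin)
  class(out) <- c("psth", "data.frame")
  out
}

#' Normalized response magnitude in the 150 ms post-stimulus window
#'
#' Maximum of a conditioned (rectified, Gaussian-smoothed) retractor
#' envelope in the window `[stim, stim + window]`, normalized to the
#' average maximum response during control stimulations.
#'
#' @param retractor_env A conditioned [sampled_trace()].
#' @param stim_time Stimulus onset (s).
#' @param control_max_mean Mean of the per-control-stimulus window maxima
#'   (> 0); see [control_max_mean()].
#' @param window Response window length in seconds (default 0.150).
#' @return Dimensionless response magnitude (>= 0).
#' @export
response_magnitude <- function(retractor_env, stim_time, control_max_mean,
                               window = 0.150) {
  stopifnot(inherits(retractor_env, "sampled_trace"))
  if (!is.numeric(control_max_mean) || control_max_mean <= 0)
    stop("`control_max_mean` must be > 0")
  tt <- trace_times(retractor_env)
  if (stim_time < tt[1L] - 1e-9 || stim_time + window > tt[length(tt)] + 1e-9)
    stop("response window exceeds the trace span")
  idx <- which(tt >= stim_time & tt <= stim_time + window)
  max(retractor_env$values[idx]) / control_max_mean
}

#' @rdname response_magnitude
#' @param control_times Times of control stimuli (quiescent animal).
#' @return `control_max_mean()`: the mean over control stimuli of the
#'   maximum envelope in their response windows.
#' @export
control_max_mean <- function(retractor_env, control_times, window = 0.150) {
  if (!length(control_times)) stop("no control stimuli supplied")
  mean(vapply(control_times, function(s) {
    tt <- trace_times(retractor_env)
    idx <- which(tt >= s & tt <= s + window)
    if (!length(idx)) stop("control window exceeds the trace span")
    max(retractor_env$values[idx])
  }, 0))
}

#' Identify control stimuli in a quiescent stretch
#'
#' Control stimuli are those delivered to the quiescent animal: stimuli
#' with no step touchdown within one mean step period on either side.
#'
#' @param stim_times Stimulus onsets (numeric or [event_series()]).
#' @param touchdowns Touchdown times (numeric or [event_series()]).
#' @param mean_period Mean step period in seconds.
#' @return Logical vector marking control stimuli.
#' @export
is_control_stim <- function(stim_times, touchdowns, mean_period) {
  st <- if (inherits(stim_times, "event_series"))
    as_event_times(stim_times, "stim_onset") else as_event_times(stim_times)
  td <- as_event_times(touchdowns, "touchdown")
  vapply(st, function(s) !any(abs(td - s) <= mean_period), TRUE)
}

#' Michelson contrast of activity around a stimulus
#'
#' Compares mean envelope activity in the windows `[stim - w, stim)` and
#' `(stim, stim + w]`: `(post - pre) / (post + pre)`, bounded in
#' \[-1, 1\]. Values above 0 indicate an increase in activity after the
#' stimulus. Both means zero yields 0 (a silent trace has no response).
#'
#' @param env A conditioned (rectified) [sampled_trace()]; negative values
#'   are an error.
#' @param stim_time Stimulus onset (s).
#' @param w Window length in seconds (default 0.1).
#' @return Dimensionless contrast in \[-1, 1\].
#' @export
michelson_contrast <- function(env, stim_time, w = 0.1) {
  stopifnot(inherits(env, "sampled_trace"))
  tt <- trace_times(env)
  if (stim_time - w < tt[1L] - 1e-9 || stim_time + w > tt[length(tt)] + 1e-9)
    stop("contrast windows exceed the trace span")
  pre_idx <- which(tt >= stim_time - w & tt < stim_time)
  post_idx <- which(tt > stim_time & tt <= stim_time + w)
  if (!length(pre_idx) || !length(post_idx))
    stop("contrast windows contain no samples")
  v <- env$values[c(pre_idx, post_idx)]
  if (any(v < -1e-9)) stop("envelope has negative values; rectify first")
  pre <- mean(env$values[pre_idx]); post <- mean(env$values[post_idx])
  if (pre + post == 0) return(0)
  (post - pre) / (post + pre)
}

#' Classify the motor response to one load stimulus
#'
#' Computes the Michelson contrast of the protractor and retractor
#' envelopes around the stimulus and classifies: `RET_ACT` (retractor
#' activation) when the retractor contrast reaches `act_threshold`;
#' `PRO_ACT` (protractor activation with retractor termination) when the
#' protractor contrast reaches `act_threshold` and the retractor contrast
#' falls below `term_threshold`; otherwise `NONE`.
#'
#' @param pro_env,ret_env Conditioned [sampled_trace()]s.
#' @param stim_time Stimulus onset (s).
#' @param act_threshold,term_threshold Contrast thresholds for activation
#'   and termination.
#' @param w Contrast window length (s).
#' @return A list of class `load_class`: `klass` (`"RET_ACT"`, `"PRO_ACT"`
#'   or `"NONE"`), `contrast_ret`, `contrast_pro`.
#' @export
classify_response <- function(pro_env, ret_env, stim_time,
                              act_threshold = 0.5, term_threshold = -0.5,
                              w = 0.1) {
  cr <- michelson_contrast(ret_env, stim_time, w)
  cp <- michelson_contrast(pro_env, stim_time, w)
  klass <- if (cr >= act_threshold) "RET_ACT"
  else if (cp >= act_threshold && cr <= term_threshold) "PRO_ACT"
  else "NONE"
  structure(list(klass = klass, contrast_ret = cr, contrast_pro = cp),
            class = "load_class")
}

#' Score and classify every stimulus of a load trial
#'
#' Convenience wrapper running [classify_response()] (and, when control
#' stimuli are given, [response_magnitude()]) over all stimuli, attaching
#' each stimulus's step-cycle phase via [phase_at()].
#'
#' @param pro_env,ret_env Conditioned [sampled_trace()]s.
#' @param stim_times Stimulus onsets.
#' @param steps A `step_cycles` data frame (for phases); may be `NULL`.
#' @param control_times Optional control stimulus onsets for magnitude
#'   normalization.
#' @inheritParams classify_response
#' @return A data frame of class `stimulus_responses`: `stim_time`,
#'   `phase`, `contrast_ret`, `contrast_pro`, `magnitude` (NA without
#'   controls), `klass`.
#' @export
score_responses <- function(pro_env, ret_env, stim_times, steps = NULL,
                            control_times = NULL, act_threshold = 0.5,
                            term_threshold = -0.5, w = 0.1) {
  st <- if (inherits(stim_times, "event_series"))
    as_event_times(stim_times, "stim_onset") else as_event_times(stim_times)
  cmax <- if (length(control_times))
    control_max_mean(ret_env, control_times) else NA_real_
  rows <- lapply(st, function(s) {
    cl <- classify_response(pro_env, ret_env, s, act_threshold,
                            term_threshold, w)
    mag <- if (is.finite(cmax)) response_magnitude(ret_env, s, cmax) else NA_real_
    data.frame(stim_time = s, contrast_ret = cl$contrast_ret,
               contrast_pro = cl$contrast_pro, magnitude = mag,
               klass = cl$klass, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$phase <- if (!is.null(steps)) phase_at(out$stim_time, steps) else NA_real_
  out <- out[, c("stim_time", "phase", "contrast_ret", "contrast_pro",
                 "magnitude", "klass")]
  class(out) <- c("stimulus_responses", "data.frame")
  out
}

#' Phase dependence of a response class
#'
#' Attaches step-cycle phases to scored stimuli and summarizes the phases
#' of one response class with a circular mean vector and Rayleigh test.
#' Needs at least `min_n` class members with defined phases; otherwise the
#' result is flagged and no test is run.
#'
#' @param responses A `stimulus_responses` data frame (see
#'   [score_responses()]), or any data frame with `stim_time` and `klass`.
#' @param steps A `step_cycles` data frame.
#' @param klass Response class to summarize.
#' @param min_n Minimum class size for the circular test.
#' @param alpha Rayleigh significance level for this analysis (default
#'   0.05).
#' @return A list of class `phase_response`: `table` (responses with
#'   phases), `summary` (a `circ_summary`, or `NULL`), `flagged`.
#' @export
response_vs_phase <- function(responses, steps, klass = "NONE", min_n = 8,
                              alpha = 0.05) {
  stopifnot(is.data.frame(responses), inherits(steps, "step_cycles"))
  responses$phase <- phase_at(responses$stim_time, steps)
  sel <- responses$klass == klass & !is.na(responses$phase)
  ph <- responses$phase[sel]
  if (length(ph) < min_n)
    return(structure(list(table = responses, summary = NULL, flagged = TRUE),
                     class = "phase_response"))
  structure(list(table = responses,
                 summary = mean_vector(ph, units = "cycle", alpha = alpha),
                 flagged = FALSE),
            class = "phase_response")
}
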