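#' Uniformly sampled signal trace
#'
#' The substrate of every trace-level operation: a vector of amplitudes
#' sampled at a fixed rate, with its start time, label and units carried as
#' metadata. Filtering operations preserve the metadata.
#'
#' @param values Numeric vector of signal amplitudes; must be finite.
#' @param fs Sampling rate in Hz (> 0).
#' @param t0 Time of the first sample in seconds.
#' @param label Free-text label (e.g. muscle or nerve name).
#' @param units Amplitude units, recorded as metadata only.
#'
#' @return An object of class `sampled_trace`: a list with elements
#'   `values`, `fs`, `t0`, `label`, `units`.
#' @examples
#' tr <- sampled_trace(sin(seq(0, 2 * pi, length.out = 100)), fs = 100)
#' trace_times(tr)[1:3]
#' @export
sampled_trace <- function(values, fs, t0 = 0, label = "", units = "a.u.") {
  if (!is.numeric(values) || length(values) < 1L)
    stop("`values` must be a non-empty numeric vector")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a positive finite scalar")
  if (!all(is.finite(values)))
    stop("trace values must all be finite")
  structure(
    list(values = as.numeric(values), fs = as.numeric(fs),
         t0 = as.numeric(t0), label = as.character(label)[1L],
         units = as.character(units)[1L]),
    class = "sampled_trace")
}

#' @rdname sampled_trace
#' @param trace A `sampled_trace`.
#' @return `trace_times()`: the vector of sample times in seconds.
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "sampled_trace"))
  trace$t0 + (seq_along(trace$values) - 1) / trace$fs
}

#' @export
print.sampled_trace <- function(x, ...) {
  dur <- length(x$values) / x$fs
  cat(sprintf("<sampled_trace> %s: %d samples @ %g Hz, t = [%.4g, %.4g] s, units %s\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$values), x$fs, x$t0, x$t0 + dur, x$units))
  invisible(x)
}

#' @export
length.sampled_trace <- function(x) length(x$values)

# internal: check two traces share the same time base
check_aligned <- function(a, b) {
  stopifnot(inherits(a, "sampled_trace"), inherits(b, "sampled_trace"))
  if (abs(a$fs - b$fs) > 1e-9 || abs(a$t0 - b$t0) > 1e-9 ||
      length(a$values) != length(b$values))
    stop("traces are not aligned (fs, t0 and length must match)")
  invisible(TRUE)
}

EVENT_KINDS <- c("touchdown", "liftoff", "stim_onset", "spike")

#' Time-stamped labelled events
#'
#' Container for gait and electrophysiological events: touchdowns, lift-offs,
#' stimulus onsets and spikes. Events are stored sorted by time; times must
#' be non-negative and, within each kind, strictly increasing.
#'
#' @param time Numeric vector of event times in seconds (non-negative).
#' @param kind Event kind, one of `"touchdown"`, `"liftoff"`, `"stim_onset"`,
#'   `"spike"`; recycled to the length of `time`.
#' @param source Label for the originating leg, nerve or channel.
#'
#' @return A data frame of class `event_series` with columns `time`, `kind`,
#'   `source`, sorted by time.
#' @examples
#' ev <- event_series(c(0, 0.83, 1.66), "touchdown", "FL")
#' events_of(ev, "touchdown")
#' @export
event_series <- function(time = numeric(), kind = character(), source = "") {
  time <- as.numeric(time)
  if (length(time) && any(!is.finite(time))) stop("event times must be finite")
  if (length(time) && any(time < 0)) stop("event times must be non-negative")
  kind <- as.character(kind)
  if (length(time)) {
    if (length(kind) == 1L) kind <- rep(kind, length(time))
    if (length(kind) != length(time)) stop("`kind` must match `time` in length")
    if (!all(kind %in% EVENT_KINDS))
      stop("unknown event kind; allowed: ", paste(EVENT_KINDS, collapse = ", "))
  } else kind <- character()
  src <- if (length(time)) rep(as.character(source), length.out = length(time)) else character()
  o <- order(time)
  df <- data.frame(time = time[o], kind = kind[o], source = src[o],
                   stringsAsFactors = FALSE)
  for (k in unique(df$kind)) {
    tk <- df$time[df$kind == k]
    if (length(tk) > 1L && any(diff(tk) <= 0))
      stop("event times must be strictly increasing within kind '", k, "'")
  }
  class(df) <- c("event_series", "data.frame")
  df
}

#' @rdname event_series
#' @param x An `event_series`.
#' @return `events_of()`: a sorted numeric vector of times of the given kind.
#' @export
events_of <- function(x, kind) {
  stopifnot(inherits(x, "event_series"))
  kind <- match.arg(kind, EVENT_KINDS)
  sort(x$time[x$kind == kind])
}

# internal: accept an event_series (optionally filtered by kind) or a bare
# sorted numeric vector of times
as_event_times <- function(x, kind = NULL) {
  if (inherits(x, "event_series")) {
    if (is.null(kind)) sort(x$time) else events_of(x, kind)
  } else {
    t <- as.numeric(x)
    if (is.unsorted(t)) t <- sort(t)
    t
  }
}

#' Read and write traces and event tables
#'
#' Traces are stored as single-column delimited text with a commented header
#' carrying `fs`, `t0`, `label` and `units`; event tables as tab-separated
#' `time_s`, `kind`, `label` columns.
#'
#' @param trace A [sampled_trace()].
#' @param events An [event_series()].
#' @param path File path.
#' @param header Named character vector of extra `# key: value` header lines.
#' @return The read object, or (for writers) `path` invisibly.
#' @export
write_trace <- function(trace, path, header = character()) {
  stopifnot(inherits(trace, "sampled_trace"))
  con <- file(path, "w"); on.exit(close(con))
  meta <- c(fs = format(trace$fs, digits = 17), t0 = format(trace$t0, digits = 17),
            label = trace$label, units = trace$units, header)
  writeLines(sprintf("# %s: %s", names(meta), meta), con)
  writeLines("value", con)
  writeLines(format(trace$values, digits = 17, trim = TRUE, scientific = FALSE), con)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  kv <- regmatches(hdr, regexec("^#\\s*([^:]+):\\s*(.*)$", hdr))
  meta <- stats::setNames(vapply(kv, `[`, "", 3L), trimws(vapply(kv, `[`, "", 2L)))
  vals <- as.numeric(body[-1L])
  sampled_trace(vals, fs = as.numeric(meta[["fs"]]),
                t0 = if ("t0" %in% names(meta)) as.numeric(meta[["t0"]]) else 0,
                label = if ("label" %in% names(meta)) meta[["label"]] else "",
                units = if ("units" %in% names(meta)) meta[["units"]] else "a.u.")
}

#' @rdname write_trace
#' @export
write_events <- function(events, path, header = character()) {
  stopifnot(inherits(events, "event_series"))
  con <- file(path, "w"); on.exit(close(con))
  if (length(header))
    writeLines(sprintf("# %s: %s", names(header), header), con)
  writeLines("time_s\tkind\tlabel", con)
  if (nrow(events))
    writeLines(sprintf("%s\t%s\t%s",
                       format(events$time, digits = 17, trim = TRUE, scientific = FALSE),
                       events$kind, events$source), con)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_events <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!nrow(df)) return(event_series())
  event_series(df$time_s, df$kind, df$label)
}
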