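#' Uniformly sampled time series
#'
#' Lightweight container for a uniformly sampled signal: a numeric vector of
#' values together with its sampling rate, start time and labels. All
#' recordings handled by the package (skin conductance, integrated nerve
#' signal, first-derivative device output) are carried in this form.
#'
#' @param values Numeric vector of samples. Must be finite and non-empty.
#' @param rate Sampling rate in samples per second (> 0).
#' @param start Time of the first sample in seconds.
#' @param units Unit label (e.g. `"uS"`, `"z"`).
#' @param channel Channel label (e.g. `"scr"`, `"sn"`).
#' @return An object of class `scr_ts`.
#' @examples
#' ts <- scr_ts(sin(seq(0, 10, by = 0.1)), rate = 10, channel = "scr")
#' ts
#' @export
scr_ts <- function(values, rate, start = 0, units = "", channel = "") {
  values <- as.numeric(values)
  if (length(values) < 1L) {
    stop("scr_ts: 'values' must contain at least one sample", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("scr_ts: all values must be finite", call. = FALSE)
  }
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0) {
    stop("scr_ts: 'rate' must be a single positive number", call. = FALSE)
  }
  structure(
    list(values = values, rate = as.numeric(rate), start = as.numeric(start),
         units = as.character(units), channel = as.character(channel)),
    class = "scr_ts"
  )
}

#' @export
print.scr_ts <- function(x, ...) {
  cat(sprintf("<scr_ts> channel='%s' n=%d rate=%g Hz start=%g s units='%s'\n",
              x$channel, length(x$values), x$rate, x$start, x$units))
  invisible(x)
}

#' @export
length.scr_ts <- function(x) length(x$values)

#' Time stamps of a time series
#'
#' @param ts An [scr_ts] object.
#' @return Numeric vector of sample times in seconds.
#' @export
ts_time <- function(ts) {
  stopifnot(inherits(ts, "scr_ts"))
  ts$start + (seq_along(ts$values) - 1) / ts$rate
}

#' @export
as.data.frame.scr_ts <- function(x, ...) {
  data.frame(time_s = ts_time(x), value = x$values)
}

ts_like <- function(ts, values, rate = ts$rate, start = ts$start) {
  scr_ts(values, rate = rate, start = start, units = ts$units,
         channel = ts$channel)
}

#' Event / stimulation schedule
#'
#' Ordered onsets with event types, subject labels, repetition indices and
#' (for stimulation-rate designs) an epoch identifier. Onsets must be
#' strictly increasing within each subject.
#'
#' @param onset_s Numeric vector of onsets in seconds.
#' @param event_type Character vector (recycled) of event labels, e.g.
#'   `"aversive"`, `"oddball"`, `"stimulation"`.
#' @param subject Character vector (recycled) of subject labels.
#' @param repetition Positive integer vector (recycled): repetition index of
#'   each event within its subject and type.
#' @param epoch_id Optional identifier grouping stimulations into
#'   constant-rate epochs.
#' @return A `data.frame` of class `event_schedule`.
#' @export
event_schedule <- function(onset_s, event_type = "event", subject = "s01",
                           repetition = NA_integer_, epoch_id = NULL) {
  n <- length(onset_s)
  if (n < 1L) stop("event_schedule: no onsets given", call. = FALSE)
  df <- data.frame(
    onset_s = as.numeric(onset_s),
    event_type = rep_len(as.character(event_type), n),
    subject = rep_len(as.character(subject), n),
    repetition = rep_len(as.integer(repetition), n),
    stringsAsFactors = FALSE
  )
  if (!is.null(epoch_id)) df$epoch_id <- rep_len(epoch_id, n)
  if (anyNA(df$repetition)) {
    # default: running index within subject x type, in onset order
    df <- df[order(df$subject, df$onset_s), , drop = FALSE]
    df$repetition <- stats::ave(df$onset_s, df$subject, df$event_type,
                                FUN = seq_along)
    df$repetition <- as.integer(df$repetition)
  }
  for (s in unique(df$subject)) {
    o <- df$onset_s[df$subject == s]
    if (any(diff(o) <= 0)) {
      stop(sprintf("event_schedule: onsets not strictly increasing for subject '%s'", s),
           call. = FALSE)
    }
  }
  if (any(df$repetition < 1L)) {
    stop("event_schedule: repetition indices must be positive", call. = FALSE)
  }
  class(df) <- c("event_schedule", "data.frame")
  df
}

#' Event-locked data epoch
#'
#' A fixed window of signal around one event onset: `pre` seconds before to
#' `post` seconds after, half-open `[onset - pre, onset + post)`, sampled at
#' 10 Hz by the standard pipeline (300 samples for the default 5 s / 25 s
#' window).
#'
#' @param values Numeric samples covering the window.
#' @param rate Sampling rate (samples/s).
#' @param onset Event onset time in seconds (in the recording's time base).
#' @param pre,post Window extent in seconds before / after the onset.
#' @param event_type,subject Event metadata labels.
#' @param index Epoch index (integer).
#' @return An object of class `scr_epoch`.
#' @export
scr_epoch <- function(values, rate, onset, pre = 5, post = 25,
                      event_type = "event", subject = "s01", index = 1L) {
  values <- as.numeric(values)
  n_expect <- round((pre + post) * rate)
  if (length(values) != n_expect) {
    stop(sprintf("scr_epoch: expected %d samples for a %g+%g s window at %g Hz, got %d",
                 n_expect, pre, post, rate, length(values)), call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("scr_epoch: all values must be finite", call. = FALSE)
  }
  structure(
    list(values = values, rate = rate, onset = onset, pre = pre, post = post,
         event_type = as.character(event_type), subject = as.character(subject),
         index = as.integer(index)),
    class = "scr_epoch"
  )
}

#' @export
print.scr_epoch <- function(x, ...) {
  cat(sprintf("<scr_epoch> subject='%s' type='%s' index=%d onset=%g s [%g, %g) s n=%d\n",
              x$subject, x$event_type, x$index, x$onset, -x$pre, x$post,
              length(x$values)))
  invisible(x)
}

#' Relative time axis of an epoch
#'
#' @param epoch An [scr_epoch].
#' @return Sample times in seconds relative to the event onset (0 at onset).
#' @export
epoch_time <- function(epoch) {
  stopifnot(inherits(epoch, "scr_epoch"))
  -epoch$pre + (seq_along(epoch$values) - 1) / epoch$rate
}
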