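#' @useDynLib scrlti, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

log_debug <- function(fmt, ...) {
  if (isTRUE(getOption("scrlti.verbose", FALSE))) {
    message(sprintf(paste0("[scrlti] ", fmt), ...))
  }
  invisible(NULL)
}

#' Causal Butterworth filtering
#'
#' Applies first-order (or higher) Butterworth high-pass and/or low-pass
#' filters in a single causal pass (no zero-phase forward-backward
#' filtering). The standard skin conductance preprocessing uses a 0.0159 Hz
#' high-pass (10 s time constant) and a 5 Hz low-pass. Filtering is causal
#' because the model's latency parameters absorb constant delays; users
#' comparing against zero-phase pipelines should expect a phase difference.
#'
#' @param ts An [scr_ts].
#' @param low_cut High-pass cutoff in Hz, or `NULL` for none.
#' @param high_cut Low-pass cutoff in Hz, or `NULL` for none.
#' @param order Filter order (default 1).
#' @return Filtered [scr_ts] of the same length and rate.
#' @examples
#' ts <- scr_ts(rnorm(500), rate = 10)
#' filt <- butter_filter(ts, low_cut = 0.0159, high_cut = 4)
#' @export
butter_filter <- function(ts, low_cut = NULL, high_cut = NULL, order = 1) {
  stopifnot(inherits(ts, "scr_ts"))
  if (is.null(low_cut) && is.null(high_cut)) {
    stop("butter_filter: at least one of 'low_cut' and 'high_cut' must be given",
         call. = FALSE)
  }
  nyq <- ts$rate / 2
  for (fc in c(low_cut, high_cut)) {
    if (fc <= 0 || fc >= nyq) {
      stop(sprintf("butter_filter: cutoff %g Hz outside (0, Nyquist = %g Hz)",
                   fc, nyq), call. = FALSE)
    }
  }
  x <- ts$values
  if (!is.null(low_cut)) {
    hp <- signal::butter(order, low_cut / nyq, type = "high")
    x <- as.numeric(signal::filter(hp, x))
  }
  if (!is.null(high_cut)) {
    lp <- signal::butter(order, high_cut / nyq, type = "low")
    x <- as.numeric(signal::filter(lp, x))
  }
  log_debug("butter_filter: low_cut=%s high_cut=%s order=%d sd %g -> %g",
            deparse(low_cut), deparse(high_cut), order,
            stats::sd(ts$values), stats::sd(x))
  ts_like(ts, x)
}

#' Equiripple FIR band-pass for raw nerve recordings
#'
#' Order-398 linear-phase equiripple (Parks-McClellan) FIR band-pass,
#' 300-4000 Hz, for raw multi-unit nerve recordings sampled at 8 kHz or
#' above. The output is delay-compensated by the filter's group delay
#' (order/2 = 199 samples) with edge padding, so burst latencies are
#' unbiased.
#'
#' @param ts An [scr_ts] sampled at >= 8000 Hz.
#' @param band Pass band in Hz (default `c(300, 4000)`).
#' @param order FIR order (default 398).
#' @return Filtered [scr_ts], same length and rate.
#' @export
fir_bandpass_nerve <- function(ts, band = c(300, 4000), order = 398) {
  stopifnot(inherits(ts, "scr_ts"))
  if (ts$rate < 2 * band[2]) {
    stop(sprintf("fir_bandpass_nerve: rate %g Hz too low for a %g Hz band edge",
                 ts$rate, band[2]), call. = FALSE)
  }
  h <- fir_nerve_coefs(ts$rate, band, order)
  n <- length(ts$values)
  gd <- order / 2
  # edge-pad so the delay-compensated output keeps the input length
  xp <- c(ts$values, rep(ts$values[n], gd))
  y <- as.numeric(stats::filter(xp, h, method = "convolution", sides = 1))
  y[is.na(y)] <- 0
  ts_like(ts, y[(gd + 1):(gd + n)])
}

fir_nerve_coefs <- function(rate, band = c(300, 4000), order = 398) {
  nyq <- rate / 2
  # transition bands scale with the pass band edges
  f <- c(0, band[1] - 100, band[1], band[2], min(band[2] + 200, nyq * 0.98), nyq) / nyq
  a <- c(0, 0, 1, 1, 0, 0)
  as.numeric(signal::remez(order, f, a))
}

#' Standardize a signal to zero mean and unit variance
#'
#' z-transforms the whole series (sample standard deviation), the standard
#' step to absorb inter-subject differences in signal scale.
#'
#' @param ts An [scr_ts] with at least 2 samples and nonzero variance.
#' @return Standardized [scr_ts].
#' @export
zscore <- function(ts) {
  stopifnot(inherits(ts, "scr_ts"))
  x <- ts$values
  if (length(x) < 2L) stop("zscore: need at least 2 samples", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) stop("zscore: zero-variance input", call. = FALSE)
  ts_like(ts, (x - mean(x)) / s)
}

#' Rectified leaky integration for burst detection
#'
#' Full-wave rectifies the signal and applies a first-order leaky
#' integrator, `y[n] = alpha * y[n-1] + (1 - alpha) * |x[n]|` with
#' `alpha = exp(-dt / tau)`, producing the smooth nonnegative envelope used
#' for sudomotor burst detection. The `(1 - alpha)` input weight normalizes
#' the recursion so a constant envelope is reproduced at unit gain.
#' Rectification precedes integration because the band-passed nerve signal
#' is zero-mean and would otherwise integrate to nothing.
#'
#' @param ts An [scr_ts].
#' @param tau Integrator time constant in seconds (default 0.1).
#' @return Nonnegative envelope as an [scr_ts].
#' @export
rectified_leaky_integrate <- function(ts, tau = 0.1) {
  stopifnot(inherits(ts, "scr_ts"))
  if (tau <= 0) stop("rectified_leaky_integrate: tau must be > 0", call. = FALSE)
  alpha <- exp(-1 / (ts$rate * tau))
  u <- (1 - alpha) * abs(ts$values)
  y <- as.numeric(stats::filter(u, alpha, method = "recursive"))
  ts_like(ts, y)
}

#' Decimate to a lower sampling rate
#'
#' Keeps the first sample of each block of `rate / target_rate` samples.
#' The caller is responsible for low-pass filtering below the target
#' Nyquist frequency beforehand (the standard chains do: Butterworth 5 Hz
#' for skin conductance, leaky integration for the nerve envelope).
#'
#' @param ts An [scr_ts].
#' @param target_rate Target rate; `rate / target_rate` must be an integer.
#' @return Decimated [scr_ts] at `target_rate`.
#' @export
downsample <- function(ts, target_rate) {
  stopifnot(inherits(ts, "scr_ts"))
  fac <- ts$rate / target_rate
  if (abs(fac - round(fac)) > 1e-9 || fac < 1) {
    stop(sprintf("downsample: rate %g is not an integer multiple of target %g",
                 ts$rate, target_rate), call. = FALSE)
  }
  fac <- round(fac)
  ts_like(ts, ts$values[seq(1, length(ts$values), by = fac)],
          rate = target_rate)
}

#' Piecewise linear detrending
#'
#' Removes an ordinary-least-squares line from each consecutive window
#' (default 5 s) to eliminate slow baseline drift from the integrated nerve
#' envelope. A final partial window is detrended likewise if it holds at
#' least 2 samples, else passed through.
#'
#' @param ts An [scr_ts].
#' @param window Window length in seconds (default 5).
#' @return Detrended [scr_ts].
#' @export
piecewise_detrend <- function(ts, window = 5) {
  stopifnot(inherits(ts, "scr_ts"))
  w <- round(window * ts$rate)
  if (w < 2) stop("piecewise_detrend: window shorter than 2 samples", call. = FALSE)
  x <- ts$values
  n <- length(x)
  out <- x
  starts <- seq(1, n, by = w)
  for (s in starts) {
    e <- min(s + w - 1, n)
    if (e - s + 1 >= 2) {
      idx <- s:e
      tt <- idx - s
      fit <- stats::lm.fit(cbind(1, tt), x[idx])
      out[idx] <- fit$residuals
    }
  }
  ts_like(ts, out)
}

#' Reconstruct skin conductance from a first-derivative recording
#'
#' Inverts a derivative-recording device by subtracting the series mean and
#' cumulatively summing. The mean subtraction forces the last sample to
#' zero, which shows up as a linear "leak" superimposed on the
#' reconstruction; the subsequent high-pass filtering removes most of it.
#'
#' @param ts An [scr_ts] holding the derivative signal.
#' @return Reconstructed [scr_ts] (arbitrary units).
#' @export
reconstruct_scr_from_derivative <- function(ts) {
  stopifnot(inherits(ts, "scr_ts"))
  x <- ts$values
  if (length(x) < 2L) stop("reconstruct_scr_from_derivative: need >= 2 samples",
                           call. = FALSE)
  ts_like(ts, cumsum(x - mean(x)))
}

#' Extract event-locked epochs
#'
#' Cuts one half-open window `[onset - pre, onset + post)` per event. Events
#' whose window does not fit inside the recording are skipped with a warning
#' and reported in the `skipped` attribute of the result.
#'
#' @param ts An [scr_ts] (10 Hz in the standard pipeline).
#' @param events An [event_schedule]; only rows matching the recording's
#'   subject are used if `subject` is given.
#' @param pre,post Window in seconds before/after each onset (defaults 5, 25).
#' @param subject Optional subject label to filter `events`.
#' @return List of [scr_epoch] objects, with attribute `skipped`: a
#'   `data.frame` of skipped events and reasons.
#' @export
extract_epochs <- function(ts, events, pre = 5, post = 25, subject = NULL) {
  stopifnot(inherits(ts, "scr_ts"), is.data.frame(events))
  ev <- as.data.frame(events)
  if (!is.null(subject)) ev <- ev[ev$subject == subject, , drop = FALSE]
  n <- length(ts$values)
  nsamp <- round((pre + post) * ts$rate)
  epochs <- list()
  skipped <- data.frame(onset_s = numeric(0), reason = character(0))
  for (k in seq_len(nrow(ev))) {
    onset <- ev$onset_s[k]
    i0 <- round((onset - pre - ts$start) * ts$rate) + 1
    i1 <- i0 + nsamp - 1
    if (i0 < 1 || i1 > n) {
      warning(sprintf("extract_epochs: window for onset %g s out of bounds; skipped",
                      onset), call. = FALSE)
      skipped <- rbind(skipped,
                       data.frame(onset_s = onset, reason = "window out of bounds"))
      next
    }
    epochs[[length(epochs) + 1L]] <- scr_epoch(
      ts$values[i0:i1], rate = ts$rate, onset = onset, pre = pre, post = post,
      event_type = ev$event_type[k], subject = ev$subject[k],
      index = if ("repetition" %in% names(ev)) ev$repetition[k] else k
    )
  }
  attr(epochs, "skipped") <- skipped
  epochs
}

#' Minimum-correct an epoch
#'
#' Subtracts the epoch minimum so the modelled response sits on a zero
#' baseline, accounting for skin conductance level maintained without
#' sudomotor firing.
#'
#' @param epoch An [scr_epoch].
#' @return The epoch with minimum 0.
#' @export
minimum_correct <- function(epoch) {
  stopifnot(inherits(epoch, "scr_epoch"))
  epoch$values <- epoch$values - min(epoch$values)
  epoch
}

#' Average epochs by group
#'
#' Pointwise mean of epochs sharing an event type (pooled across subjects)
#' or a subject x event type cell, yielding the grand-average and
#' per-subject responses on which canonical and subject-level response
#' functions are estimated.
#'
#' @param epochs List of [scr_epoch] objects with equal windows.
#' @param by `"event_type"` (pooled) or `"subject_event_type"`.
#' @return Named list of averaged [scr_epoch] objects (subject `"all"` for
#'   pooled averages). Empty groups are omitted.
#' @export
average_epochs <- function(epochs, by = c("event_type", "subject_event_type")) {
  by <- match.arg(by)
  if (length(epochs) < 1L) stop("average_epochs: no epochs", call. = FALSE)
  key <- vapply(epochs, function(e) {
    if (by == "event_type") e$event_type else paste(e$subject, e$event_type, sep = ".")
  }, character(1))
  out <- list()
  for (g in unique(key)) {
    grp <- epochs[key == g]
    m <- rowMeans(vapply(grp, function(e) e$values, numeric(length(grp[[1]]$values))))
    proto <- grp[[1]]
    out[[g]] <- scr_epoch(m, rate = proto$rate, onset = 0, pre = proto$pre,
                          post = proto$post, event_type = proto$event_type,
                          subject = if (by == "event_type") "all" else proto$subject,
                          index = length(grp))
  }
  out
}

#' Flag clipped (saturated) intervals
#'
#' Flags maximal runs of at least `min_run` consecutive samples with
#' `|x| >= level`, the signature of an amplifier saturating. Epochs
#' overlapping a flagged interval should be excluded from analysis (see
#' [epoch_overlaps_interval()]).
#'
#' @param ts An [scr_ts].
#' @param level Saturation level in signal units (> 0).
#' @param min_run Minimum run length in samples (default 3).
#' @return `data.frame` with columns `start_idx`, `end_idx`, `start_s`,
#'   `end_s`; zero rows if nothing is flagged.
#' @export
detect_clipping <- function(ts, level, min_run = 3L) {
  stopifnot(inherits(ts, "scr_ts"))
  if (level <= 0) stop("detect_clipping: level must be > 0", call. = FALSE)
  sat <- abs(ts$values) >= level
  r <- rle(sat)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_run
  out <- data.frame(start_idx = starts[keep], end_idx = ends[keep])
  out$start_s <- ts$start + (out$start_idx - 1) / ts$rate
  out$end_s <- ts$start + (out$end_idx - 1) / ts$rate
  out
}

#' Does an epoch overlap a flagged interval?
#'
#' @param epoch An [scr_epoch].
#' @param flags Output of [detect_clipping()].
#' @return Logical.
#' @export
epoch_overlaps_interval <- function(epoch, flags) {
  stopifnot(inherits(epoch, "scr_epoch"))
  if (nrow(flags) == 0L) return(FALSE)
  w0 <- epoch$onset - epoch$pre
  w1 <- epoch$onset + epoch$post
  any(flags$start_s < w1 & flags$end_s >= w0)
}
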