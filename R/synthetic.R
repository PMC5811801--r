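#' Configuration for the synthetic-data generator
#'
#' Builds a validated configuration describing either an intraneural
#' *recording*-style dataset (`style = "exp1"`: sparse sensory events, a
#' sudomotor channel and a skin conductance channel per subject) or an
#' intraneural *stimulation*-style dataset (`style = "exp2"`:
#' constant-rate stimulation epochs recorded through a first-derivative
#' device under regional anesthesia).
#'
#' Defaults encode the study conditions the generator emulates: 6 subjects
#' with 20 aversive and 10 oddball events at >= 30 s spacing for `exp1`;
#' 4 subjects sharing 15 constant-rate epochs (six at ~0.1 Hz, three at
#' ~0.2 Hz, one at ~0.5 Hz, one at ~1 Hz, two at ~1.5 Hz, two at ~10 Hz,
#' with ~39 / ~77 / ~180 events per epoch in the low / medium / high rate
#' ranges) for `exp2`. Burst and response-function truth default to the
#' canonical parameter sets estimated from averaged responses. Gains are
#' log-normal between epochs (SD 0.3) around `gain_mean`; measurement
#' noise is white Gaussian at 5% of the clean signal SD; baseline drift is
#' a 0.005 Hz sinusoid at 10% of signal SD. A multiplicative gain-depletion
#' nonlinearity (each burst scales the available gain by `1 - delta`,
#' recovering with time constant `tau_rec`) is enabled by default for
#' `exp2`, where stimulation is fast enough to engage it.
#'
#' @param style `"exp1"` or `"exp2"`.
#' @param ... Overrides for any default field (see Details in the package
#'   vignette).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(style = c("exp1", "exp2"), ...) {
  style <- match.arg(style)
  cfg <- list(
    style = style,
    seed = 1L,
    rate = 10,
    # truth: canonical third-order response function and Gaussian bursts
    theta = if (style == "exp1") scrf_params(1.3277, 1.1205, 0.1084, -0.4265)
            else scrf_params(2.3051, 2.5653, 0.1517, -0.0058),
    theta_subject_sd = 0.1,   # log-scale spread of theta1..3 across subjects
    theta4_subject_sd = 0.1,  # additive spread of the delay (s)
    bursts = list(
      aversive = burst_params(A = 0.7814, mu = 1.6850, sigma = 0.3051, c = 0.1567),
      oddball = burst_params(A = 0.6589, mu = 1.6785, sigma = 0.2471, c = 0)
    ),
    sigma_in = 0.3,           # dispersion of stimulation input Gaussians (s)
    # gain model
    gain_mean = 1,
    gain_sd = 0.3,            # log-normal between-epoch SD
    gain_trend = 0,           # additive change per repetition
    # noise and drift
    noise_sd = 0.05,          # SCR measurement noise, fraction of signal SD
    sn_noise_sd = 0.1,        # spontaneous sudomotor activity, fraction of
                              # the burst peak (drives the SCR)
    sn_interference_sd = 0.05, # non-sudomotor fiber activity, fraction of
                              # the burst peak (contaminates the nerve
                              # channel only)
    drift_amp = 0.1,          # drift amplitude as a fraction of signal SD
    drift_freq = 0.005,       # Hz
    # depletion nonlinearity
    depletion = list(enabled = (style == "exp2"), delta = 0.3, tau_rec = 20),
    # derivative-recording device (exp2)
    device = list(enabled = TRUE, rise_tau = 0.3, decay_tau = 3, hp_cut = 0.7),
    raw_nerve = FALSE
  )
  if (style == "exp1") {
    cfg$n_subjects <- 6L
    cfg$events <- list(aversive = 20L, oddball = 10L)
    cfg$min_gap <- 30
    cfg$gap_jitter <- 10
    cfg$lead_in <- 40
    cfg$tail <- 35
  } else {
    cfg$rates_by_subject <- list(
      s01 = c(0.1, 0.1, 0.2, 10),
      s02 = c(0.1, 0.2, 0.5, 1),
      s03 = c(0.1, 0.1, 1.5, 10),
      s04 = c(0.1, 0.2, 1.5)
    )
    cfg$events_per_epoch <- NA    # derived from rate unless overridden
    cfg$rate_jitter <- 0.05       # fractional jitter of inter-stimulus intervals
    cfg$epoch_pad <- c(5, 30)     # seconds before first / after last onset
  }
  over <- list(...)
  bad <- setdiff(names(over), c(names(cfg), "n_subjects"))
  if (length(bad)) {
    stop("synth_config: unknown fields: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(over)] <- over
  validate_synth_config(cfg)
  class(cfg) <- "synth_config"
  cfg
}

validate_synth_config <- function(cfg) {
  stopifnot(cfg$rate > 0, cfg$gain_sd >= 0, cfg$noise_sd >= 0,
            cfg$sn_noise_sd >= 0, cfg$sn_interference_sd >= 0,
            cfg$drift_amp >= 0, cfg$sigma_in > 0,
            cfg$theta_subject_sd >= 0, is.numeric(cfg$seed))
  if (cfg$depletion$enabled) {
    if (cfg$depletion$delta < 0 || cfg$depletion$delta >= 1 ||
        cfg$depletion$tau_rec <= 0) {
      stop("synth_config: depletion needs delta in [0,1) and tau_rec > 0",
           call. = FALSE)
    }
  }
  if (cfg$style == "exp2") {
    rates <- unlist(cfg$rates_by_subject)
    if (any(rates <= 0)) stop("synth_config: stimulation rates must be > 0",
                              call. = FALSE)
  }
  invisible(cfg)
}

default_events_per_epoch <- function(rate) {
  if (rate < 0.12) 39L else if (rate <= 0.6) 77L else 180L
}

#' Generate an event / stimulation schedule
#'
#' For `exp1`-style configurations: per subject, event onsets separated by
#' the minimum gap plus a uniform jitter, aversive events followed by
#' oddball events, with repetition indices counted within subject and
#' event type. For `exp2`-style configurations: per subject, consecutive
#' constant-rate stimulation epochs with near-periodic onsets (inter-onset
#' intervals jittered by up to `rate_jitter`), each padded before the first
#' and after the last onset. Reproducible from `cfg$seed`.
#'
#' @param cfg A [synth_config].
#' @return For `exp1`: an [event_schedule]. For `exp2`: an
#'   [event_schedule] with `epoch_id`, carrying an `epochs` attribute
#'   (`data.frame` of epoch spans and nominal rates).
#' @export
make_schedule <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed + 1L, {
    if (cfg$style == "exp1") {
      rows <- list()
      for (s in seq_len(cfg$n_subjects)) {
        subj <- sprintf("s%02d", s)
        t <- cfg$lead_in
        for (type in names(cfg$events)) {
          n <- cfg$events[[type]]
          for (k in seq_len(n)) {
            rows[[length(rows) + 1L]] <- data.frame(
              onset_s = t, event_type = type, subject = subj,
              repetition = k, stringsAsFactors = FALSE)
            t <- t + cfg$min_gap + stats::runif(1, 0, cfg$gap_jitter)
          }
        }
      }
      df <- do.call(rbind, rows)
      sched <- event_schedule(df$onset_s, df$event_type, df$subject, df$repetition)
      attr(sched, "durations") <- stats::aggregate(
        onset_s ~ subject, data = df, FUN = function(o) max(o) + cfg$tail)
      sched
    } else {
      rows <- list()
      spans <- list()
      for (subj in names(cfg$rates_by_subject)) {
        t <- 0
        for (e in seq_along(cfg$rates_by_subject[[subj]])) {
          rate <- cfg$rates_by_subject[[subj]][e]
          n <- if (is.na(cfg$events_per_epoch[1])) default_events_per_epoch(rate)
               else cfg$events_per_epoch
          id <- sprintf("%s_e%02d", subj, e)
          t0 <- t
          on <- t + cfg$epoch_pad[1] +
            cumsum(c(0, (1 / rate) * (1 + stats::runif(n - 1, -cfg$rate_jitter,
                                                       cfg$rate_jitter))))
          t <- max(on) + cfg$epoch_pad[2]
          rows[[length(rows) + 1L]] <- data.frame(
            onset_s = on, event_type = "stimulation", subject = subj,
            repetition = seq_len(n), epoch_id = id, stringsAsFactors = FALSE)
          spans[[length(spans) + 1L]] <- data.frame(
            epoch_id = id, subject = subj, t_start = t0, t_end = t,
            rate_nominal = rate, n_events = n, stringsAsFactors = FALSE)
        }
      }
      df <- do.call(rbind, rows)
      sched <- event_schedule(df$onset_s, df$event_type, df$subject,
                              df$repetition, epoch_id = df$epoch_id)
      attr(sched, "epochs") <- do.call(rbind, spans)
      sched
    }
  })
}

#' Synthesize a sudomotor-nerve envelope recording
#'
#' Sum of Gaussian bursts (one per scheduled event, centred `mu` seconds
#' after each onset) on a constant baseline, plus white Gaussian noise and
#' an optional slow sinusoidal drift, sampled at `rate`. Noise and drift
#' draw from the current RNG state; wrap in a seed for reproducibility.
#'
#' @param schedule [event_schedule] rows for one subject.
#' @param bursts A [burst_params] or a named list of them keyed by event
#'   type.
#' @param noise_sd Noise SD as a fraction of the tallest burst peak.
#' @param rate Sampling rate (default 10 Hz).
#' @param duration Recording length in seconds (default: last onset + 35 s).
#' @param drift_amp Drift amplitude as a fraction of the clean signal SD.
#' @param drift_freq Drift frequency in Hz.
#' @param extra Optional numeric vector (length of the recording) added to
#'   the clean signal before drift and noise, e.g. spontaneous activity
#'   shared with the skin conductance drive.
#' @return An [scr_ts] (channel `"sn"`).
#' @export
synth_sn <- function(schedule, bursts, noise_sd = 0, rate = 10,
                     duration = NULL, drift_amp = 0, drift_freq = 0.005,
                     extra = NULL) {
  ev <- as.data.frame(schedule)
  if (is.null(duration)) duration <- max(ev$onset_s) + 35
  n <- round(duration * rate)
  tgrid <- (seq_len(n) - 1) / rate
  if (inherits(bursts, "burst_params")) {
    bursts <- stats::setNames(rep(list(bursts), length(unique(ev$event_type))),
                              unique(ev$event_type))
  }
  v <- numeric(n)
  base <- 0
  peak <- 0
  for (k in seq_len(nrow(ev))) {
    p <- bursts[[ev$event_type[k]]]
    if (is.null(p)) stop("synth_sn: no burst parameters for event type ",
                         ev$event_type[k], call. = FALSE)
    v <- v + p$A * stats::dnorm(tgrid, ev$onset_s[k] + p$mu, p$sigma)
    peak <- max(peak, p$A / (sqrt(2 * pi) * p$sigma))
  }
  base <- mean(vapply(bursts, function(p) p$c, numeric(1)))
  v <- v + base
  if (!is.null(extra)) v <- v + rep_len(extra, n)
  clean_sd <- stats::sd(v)
  if (drift_amp > 0 && clean_sd > 0) {
    v <- v + drift_amp * clean_sd *
      sin(2 * pi * drift_freq * tgrid + stats::runif(1, 0, 2 * pi))
  }
  if (noise_sd > 0) v <- v + stats::rnorm(n, 0, noise_sd * peak)
  scr_ts(v, rate = rate, start = 0, units = "z", channel = "sn")
}

#' Synthesize a skin conductance recording
#'
#' Drives the third-order response function with a gain-weighted train of
#' Gaussian inputs (one per scheduled onset) and adds white noise and an
#' optional slow drift. By superposition this equals the sum of per-onset
#' responses, each scaled by its effective gain, but is computed in a
#' single ODE pass over the gain-weighted input. The generator emits a
#' positive-going skin conductance signal (simulation gain `-g`), so
#' under the ODE's sign convention fits against it recover gains of
#' magnitude `g` with negative sign.
#'
#' @param schedule [event_schedule] rows for one subject.
#' @param theta An [scrf_params] truth set (must be stable).
#' @param gains Effective gain per onset (recycled).
#' @param areas Input area per onset (recycled; burst area `A` for
#'   recording-style data, 1 for unit stimulation inputs).
#' @param input_delay Centre offset of each input Gaussian relative to its
#'   onset (burst latency `mu` for recording-style data, 0 for stimulation;
#'   recycled per onset).
#' @param sigma_in Dispersion of the input Gaussians (s; recycled per onset).
#' @param noise_sd Noise SD as a fraction of the clean signal SD.
#' @param rate,duration Sampling rate and length (default: last onset + 35 s).
#' @param drift_amp,drift_freq Drift scale (fraction of signal SD) and
#'   frequency.
#' @param extra_input Optional numeric vector added to the gain-weighted
#'   input train before simulation (baseline nerve tone and spontaneous
#'   activity that drive the skin conductance alongside the event bursts).
#' @return An [scr_ts] (channel `"scr"`) with the clean signal in attribute
#'   `clean`.
#' @export
synth_scr <- function(schedule, theta, gains = 1, areas = 1, input_delay = 0,
                      sigma_in = 0.3, noise_sd = 0, rate = 10, duration = NULL,
                      drift_amp = 0, drift_freq = 0.005, extra_input = NULL) {
  ev <- as.data.frame(schedule)
  if (!scrf_stable(theta)) stop("synth_scr: unstable theta", call. = FALSE)
  if (is.null(duration)) duration <- max(ev$onset_s) + 35
  n <- round(duration * rate)
  tgrid <- (seq_len(n) - 1) / rate
  K <- nrow(ev)
  gains <- rep_len(gains, K)
  areas <- rep_len(areas, K)
  input_delay <- rep_len(input_delay, K)
  sigma_in <- rep_len(sigma_in, K)
  w <- numeric(n)
  for (k in seq_len(K)) {
    w <- w + gains[k] * areas[k] *
      stats::dnorm(tgrid, ev$onset_s[k] + input_delay[k], sigma_in[k])
  }
  if (!is.null(extra_input)) w <- w + rep_len(extra_input, n)
  u <- scr_ts(w, rate = rate, start = 0, channel = "weighted_input")
  x <- scrf_simulate(theta, u, gain = -1)$values
  clean <- x
  out <- x
  clean_sd <- stats::sd(clean)
  if (drift_amp > 0 && clean_sd > 0) {
    out <- out + drift_amp * clean_sd *
      sin(2 * pi * drift_freq * tgrid + stats::runif(1, 0, 2 * pi))
  }
  if (noise_sd > 0 && clean_sd > 0) {
    out <- out + stats::rnorm(n, 0, noise_sd * clean_sd)
  }
  res <- scr_ts(out, rate = rate, start = 0, units = "uS", channel = "scr")
  attr(res, "clean") <- clean
  res
}

#' Apply the gain-depletion nonlinearity
#'
#' Multiplicative depletion of the available response gain: a state `s`
#' starts at 1; each burst consumes a fraction `delta` (`s <- s * (1 -
#' delta)` after the burst) and `s` relaxes back toward 1 between bursts as
#' `1 - (1 - s) * exp(-dt / tau_rec)`. The effective gain of each onset is
#' the configured gain times the pre-onset state. At inter-onset intervals
#' long relative to `tau_rec` the state is fully recovered and gains are
#' unchanged; above ~0.6 Hz the state is driven down and later responses
#' shrink — the direction of the high-rate model breakdown.
#'
#' @param gains Per-onset gains (numeric).
#' @param onsets Onset times in seconds (same length, increasing).
#' @param delta Depleted fraction per burst, in \[0, 1).
#' @param tau_rec Recovery time constant in seconds (> 0).
#' @return Numeric vector of effective gains.
#' @export
apply_depletion <- function(gains, onsets, delta, tau_rec) {
  stopifnot(length(gains) == length(onsets), delta >= 0, delta < 1,
            tau_rec > 0)
  s <- 1
  out <- numeric(length(gains))
  for (k in seq_along(onsets)) {
    if (k > 1) s <- 1 - (1 - s) * exp(-(onsets[k] - onsets[k - 1]) / tau_rec)
    out[k] <- gains[k] * s
    s <- s * (1 - delta)
  }
  out
}

#' Emulate a first-derivative recording device
#'
#' Models an AC-coupled skin conductance amplifier that effectively records
#' the first derivative of the conductance: a first-order low-pass at
#' `1 / (2 * pi * rise_tau)` Hz (finite rise time), a first-order
#' high-pass with decay constant `decay_tau` (the output follows changes
#' and decays back), and a first-order high-pass at `hp_cut` Hz (the
#' acquisition AC coupling). No explicit differencing is applied: in the
#' skin conductance band (well below `hp_cut`) the AC coupling itself acts
#' as the differentiator, `|H(f)| ~ f / hp_cut`, which is what a
#' cumulative-sum reconstruction subsequently inverts. All stages are
#' causal single-pass Butterworth sections, so the chain is linear:
#' scaling the input scales the output exactly. Note that the device is
#' blind to content below its slowest high-pass corner — the slowly
#' accumulating conductance level under sustained stimulation is not
#' recoverable from its output.
#'
#' @param scr Input [scr_ts] at >= 10 Hz.
#' @param rise_tau Rise time constant in seconds (default 0.3).
#' @param decay_tau Decay time constant in seconds (default 3).
#' @param hp_cut Hardware high-pass cutoff in Hz (default 0.7).
#' @return Device output as an [scr_ts] (channel `"scr_deriv"`).
#' @export
emulate_derivative_recorder <- function(scr, rise_tau = 0.3, decay_tau = 3,
                                        hp_cut = 0.7) {
  stopifnot(inherits(scr, "scr_ts"))
  if (scr$rate < 10) stop("emulate_derivative_recorder: need rate >= 10 Hz",
                          call. = FALSE)
  y <- scr_ts(scr$values, rate = scr$rate, start = scr$start,
              channel = "scr_deriv")
  y <- butter_filter(y, high_cut = 1 / (2 * pi * rise_tau))
  y <- butter_filter(y, low_cut = 1 / (2 * pi * decay_tau))
  y <- butter_filter(y, low_cut = hp_cut)
  y
}

#' Synthesize a raw high-rate nerve recording
#'
#' Band-limited noise bursts under Gaussian envelopes at the scheduled
#' onsets, on top of broadband background noise, sampled at `rate`
#' (default 10 kHz). Only intended for exercising the FIR band-pass and
#' the rectified leaky integrator; full-length raw traces are large, which
#' is why datasets include them only on request.
#'
#' @param schedule [event_schedule] rows for one subject.
#' @param burst A [burst_params]; the envelope uses `mu`/`sigma`, the burst
#'   carrier SD scales with `A`.
#' @param rate Sampling rate (default 10000 Hz).
#' @param duration Length in seconds.
#' @param noise_sd Background noise SD relative to the burst carrier SD.
#' @return An [scr_ts] (channel `"sn_raw"`).
#' @export
synth_raw_nerve <- function(schedule, burst, rate = 10000, duration = NULL,
                            noise_sd = 0.2) {
  ev <- as.data.frame(schedule)
  if (is.null(duration)) duration <- max(ev$onset_s) + 5
  n <- round(duration * rate)
  tgrid <- (seq_len(n) - 1) / rate
  env <- numeric(n)
  for (k in seq_len(nrow(ev))) {
    env <- env + exp(-(tgrid - ev$onset_s[k] - burst$mu)^2 / (2 * burst$sigma^2))
  }
  carrier <- stats::rnorm(n)
  # band-limit the carrier into the multi-unit band
  bp <- signal::butter(2, c(300, min(4000, rate / 2 * 0.9)) / (rate / 2), "pass")
  carrier <- as.numeric(signal::filter(bp, carrier))
  v <- burst$A * env * carrier + noise_sd * burst$A * stats::rnorm(n)
  scr_ts(v, rate = rate, start = 0, units = "uV", channel = "sn_raw")
}

#' Generate a complete synthetic dataset
#'
#' Composes the schedule, truth parameters, signal channels and noise into
#' a dataset with full ground truth. `exp1`-style datasets carry a
#' sudomotor envelope channel and a skin conductance channel per subject;
#' `exp2`-style datasets carry the derivative-device output (and the
#' pre-device skin conductance, kept as part of the truth record) per
#' subject, plus the stimulation epochs table. Regeneration from the same
#' configuration is bit-identical.
#'
#' @param cfg A [synth_config].
#' @return A list of class `scr_dataset`: `style`, `cfg`, `schedule`,
#'   `epochs` (exp2), `subjects` (named list of channel [scr_ts]s),
#'   `truth` (per-subject `theta`, per-onset gain table, burst parameters),
#'   `seed`.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  validate_synth_config(cfg)
  sched <- make_schedule(cfg)
  subj_names <- unique(as.data.frame(sched)$subject)

  # per-subject truth response functions
  thetas <- with_seed(cfg$seed + 2L, {
    out <- list()
    for (s in subj_names) {
      th <- cfg$theta
      if (cfg$theta_subject_sd > 0 || cfg$theta4_subject_sd > 0) {
        out[[s]] <- scrf_params(
          th$theta1 * exp(stats::rnorm(1, 0, cfg$theta_subject_sd)),
          th$theta2 * exp(stats::rnorm(1, 0, cfg$theta_subject_sd)),
          th$theta3 * exp(stats::rnorm(1, 0, cfg$theta_subject_sd)),
          th$theta4 + stats::rnorm(1, 0, cfg$theta4_subject_sd))
      } else {
        out[[s]] <- th
      }
    }
    out
  })

  ev_all <- as.data.frame(sched)
  gain_tab <- with_seed(cfg$seed + 3L, {
    rows <- list()
    for (s in subj_names) {
      ev <- ev_all[ev_all$subject == s, , drop = FALSE]
      ev <- ev[order(ev$onset_s), , drop = FALSE]
      if (cfg$style == "exp1") {
        # one epoch per event: per-event log-normal gain + repetition trend
        g <- cfg$gain_mean * exp(stats::rnorm(nrow(ev), 0, cfg$gain_sd)) +
          cfg$gain_trend * (ev$repetition - 1)
      } else {
        # one gain per stimulation epoch, shared by its onsets
        g <- numeric(nrow(ev))
        for (id in unique(ev$epoch_id)) {
          i <- ev$epoch_id == id
          g[i] <- cfg$gain_mean * exp(stats::rnorm(1, 0, cfg$gain_sd)) +
            cfg$gain_trend * (ev$repetition[i] - 1)
        }
      }
      g_eff <- if (cfg$depletion$enabled) {
        apply_depletion(g, ev$onset_s, cfg$depletion$delta, cfg$depletion$tau_rec)
      } else g
      ev$gain <- g
      ev$gain_eff <- g_eff
      rows[[length(rows) + 1L]] <- ev
    }
    do.call(rbind, rows)
  })

  subjects <- with_seed(cfg$seed + 4L, {
    out <- list()
    for (s in subj_names) {
      ev <- gain_tab[gain_tab$subject == s, , drop = FALSE]
      duration <- if (cfg$style == "exp1") {
        dur <- attr(sched, "durations")
        dur$onset_s[dur$subject == s]
      } else {
        spans <- attr(sched, "epochs")
        max(spans$t_end[spans$subject == s])
      }
      chan <- list()
      if (cfg$style == "exp1") {
        burst_of <- function(type, field) {
          vapply(type, function(ty) cfg$bursts[[ty]][[field]], numeric(1))
        }
        peak <- max(vapply(cfg$bursts, function(p)
          p$A / (sqrt(2 * pi) * p$sigma), numeric(1)))
        nsamp <- round(duration * cfg$rate)
        # spontaneous sudomotor activity appears in the nerve channel AND
        # drives the skin conductance; interference from non-sudomotor
        # fibers contaminates the nerve channel only
        spont <- stats::rnorm(nsamp, 0, cfg$sn_noise_sd * peak)
        base <- mean(vapply(cfg$bursts, function(p) p$c, numeric(1)))
        chan$sn <- synth_sn(ev, cfg$bursts, noise_sd = cfg$sn_interference_sd,
                            rate = cfg$rate, duration = duration,
                            drift_amp = cfg$drift_amp,
                            drift_freq = cfg$drift_freq, extra = spont)
        chan$scr <- synth_scr(ev, thetas[[s]], gains = ev$gain_eff,
                              areas = burst_of(ev$event_type, "A"),
                              input_delay = burst_of(ev$event_type, "mu"),
                              sigma_in = burst_of(ev$event_type, "sigma"),
                              noise_sd = cfg$noise_sd, rate = cfg$rate,
                              duration = duration, drift_amp = cfg$drift_amp,
                              drift_freq = cfg$drift_freq,
                              extra_input = cfg$gain_mean * (base + spont))
        if (isTRUE(cfg$raw_nerve)) {
          chan$sn_raw <- synth_raw_nerve(ev, cfg$bursts[[1]],
                                         duration = duration)
        }
      } else {
        chan$scr <- synth_scr(ev, thetas[[s]], gains = ev$gain_eff,
                              areas = 1, input_delay = 0,
                              sigma_in = cfg$sigma_in,
                              noise_sd = cfg$noise_sd, rate = cfg$rate,
                              duration = duration, drift_amp = cfg$drift_amp,
                              drift_freq = cfg$drift_freq)
        chan$deriv <- if (cfg$device$enabled) {
          emulate_derivative_recorder(chan$scr,
                                      rise_tau = cfg$device$rise_tau,
                                      decay_tau = cfg$device$decay_tau,
                                      hp_cut = cfg$device$hp_cut)
        } else {
          scr_ts(c(0, diff(chan$scr$values)), rate = cfg$rate,
                 channel = "scr_deriv")
        }
      }
      out[[s]] <- chan
    }
    out
  })

  structure(list(
    style = cfg$style, cfg = cfg, schedule = sched,
    epochs = attr(sched, "epochs"), subjects = subjects,
    truth = list(theta = thetas, gains = gain_tab, bursts = cfg$bursts,
                 theta_canonical = cfg$theta),
    seed = cfg$seed
  ), class = "scr_dataset")
}

#' @export
print.scr_dataset <- function(x, ...) {
  cat(sprintf("<scr_dataset> style=%s subjects=%d events=%d seed=%d\n",
              x$style, length(x$subjects), nrow(as.data.frame(x$schedule)),
              x$seed))
  invisible(x)
}

#' Hash of a dataset
#'
#' Stable content hash of a generated dataset, for checking bit-identical
#' regeneration from a configuration.
#'
#' @param ds An `scr_dataset`.
#' @return Character hash.
#' @export
dataset_hash <- function(ds) rlang::hash(ds)
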