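#' Pipeline configuration
#'
#' Collects the fixed constants of the analysis chains: filter cutoffs and
#' order, the analysis rate, the epoch window, the input-train dispersion,
#' rate-class thresholds, fitter settings, the gain mode, and the constants
#' of the derivative-recording device assumed in the stimulation
#' experiment's observation model. Serializes losslessly (plain list), and
#' [config_hash()] gives a stable hash that is recorded in every report.
#'
#' @param ... Overrides for any default field.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    scr_low_cut = 0.0159,   # Hz, high-pass (10 s time constant)
    scr_high_cut = 5,       # Hz, low-pass (skipped when >= Nyquist)
    filter_order = 1,
    target_rate = 10,       # Hz, analysis rate
    epoch_pre = 5,          # s
    epoch_post = 25,        # s
    sigma_in = 0.3,         # s, stimulation input Gaussians
    detrend_window = NULL,  # s, nerve-envelope detrending; NULL disables.
                            # Piecewise detrending forces every window of
                            # the nerve envelope to integrate to zero,
                            # which cancels the slow response the model
                            # must predict; the observation-model
                            # high-pass already removes baseline drift.
    leaky_tau = 0.1,        # s, burst-detection integrator
    rate_thresholds = c(low = 0.12, medium_lo = 0.19, medium_hi = 0.6,
                        exclude = 5),
    clip_level = NULL,      # signal units; NULL disables clipping exclusion
    n_starts = 5,
    seed = 1,
    substeps = 10,
    gain_mode = "per_epoch",
    gain_intercept = TRUE,  # affine gain regression (see vignette)
    ir_duration = 30,       # s, reported impulse responses
    pred_ir_duration = 90,  # s, kernel length for whole-recording prediction
    # observation model for the stimulation experiment: "device" passes
    # model predictions through the derivative recorder + reconstruction +
    # band-pass before residuals; "filters" omits the device; "none"
    # compares raw model output with the data
    exp2_observation = "device",
    device_rise_tau = 0.3,  # s
    device_decay_tau = 3,   # s
    device_hp_cut = 0.7     # Hz
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("pipeline_config: unknown fields: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  cfg[names(over)] <- over
  stopifnot(cfg$scr_low_cut > 0, cfg$target_rate > 0, cfg$epoch_pre >= 0,
            cfg$epoch_post > 0, cfg$sigma_in > 0, cfg$n_starts >= 1)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Stable hash of a configuration
#'
#' @param config Any serializable configuration object.
#' @return Character hash.
#' @export
config_hash <- function(config) rlang::hash(unclass(config))

epoch_as_ts <- function(e) scr_ts(e$values, rate = e$rate, start = 0)

slice_ts <- function(ts, t0, t1) {
  i0 <- round((t0 - ts$start) * ts$rate) + 1
  i1 <- min(round((t1 - ts$start) * ts$rate), length(ts$values))
  scr_ts(ts$values[i0:i1], rate = ts$rate, start = t0, units = ts$units,
         channel = ts$channel)
}

scr_filter_chain <- function(ts, config) {
  nyq <- ts$rate / 2
  high <- if (config$scr_high_cut < nyq) config$scr_high_cut else NULL
  butter_filter(ts, low_cut = config$scr_low_cut, high_cut = high,
                order = config$filter_order)
}

preprocess_scr <- function(ts, config) {
  ts <- scr_filter_chain(ts, config)
  ts <- zscore(ts)
  downsample(ts, config$target_rate)
}

preprocess_sn <- function(ts, config) {
  if (ts$rate >= 8000) {
    ts <- fir_bandpass_nerve(ts)
    ts <- zscore(ts)
    ts <- rectified_leaky_integrate(ts, tau = config$leaky_tau)
    ts <- downsample(ts, config$target_rate)
  } else {
    # channel already holds the integrated envelope at (a multiple of) the
    # analysis rate
    ts <- zscore(ts)
    if (ts$rate > config$target_rate) ts <- downsample(ts, config$target_rate)
  }
  if (!is.null(config$detrend_window) && config$detrend_window > 0) {
    ts <- piecewise_detrend(ts, window = config$detrend_window)
  }
  ts
}

# observation model of the recording-experiment analysis: the data were
# causally band-pass filtered, so model predictions are passed through the
# same filters before being compared with them
exp1_obs_transform <- function(config) {
  force(config)
  function(p) {
    scr_filter_chain(scr_ts(p, rate = config$target_rate), config)$values
  }
}

# observation model of the stimulation experiment: derivative-recording
# device, cumsum reconstruction and the preprocessing band-pass (all with
# known, documented constants); linear, so gains keep their meaning
exp2_obs_transform <- function(config) {
  force(config)
  mode <- config$exp2_observation
  function(p) {
    if (mode == "none") return(p)
    ts <- scr_ts(p, rate = config$target_rate)
    if (mode == "device") {
      ts <- emulate_derivative_recorder(ts, rise_tau = config$device_rise_tau,
                                        decay_tau = config$device_decay_tau,
                                        hp_cut = config$device_hp_cut)
      ts <- reconstruct_scr_from_derivative(ts)
    }
    scr_filter_chain(ts, config)$values
  }
}

affine_fixed <- function(preds, obs, intercept) {
  p <- unlist(preds); o <- unlist(obs)
  if (intercept) {
    pc <- p - mean(p)
    den <- sum(pc^2)
    g <- if (den > 0) sum(pc * (o - mean(o))) / den else NA_real_
    c(gain = g, intercept = mean(o) - g * mean(p))
  } else {
    den <- sum(p^2)
    c(gain = if (den > 0) sum(p * o) / den else NA_real_, intercept = 0)
  }
}

#' Run the intraneural-recording analysis pipeline
#'
#' End-to-end analysis of a recording-style dataset: preprocess the skin
#' conductance and nerve channels, cut event epochs, average per event type
#' (pooled and per subject), fit the Gaussian burst model and the ODE
#' response function on the averages (model predictions are compared with
#' the data through the same causal filters the data passed), predict every
#' epoch by convolving the whole preprocessed nerve recording with the
#' fitted impulse response, estimate per-epoch and per-subject fixed gains,
#' quantify explained variance, partition it across canonical /
#' subject-level response functions, and regress the per-epoch gain on
#' event repetition.
#'
#' @param dataset An `scr_dataset` from [generate_dataset()] (style
#'   `"exp1"`), or a list with the same `subjects` / `schedule` shape read
#'   from files.
#' @param config A [pipeline_config].
#' @return A list of class `scr_report`.
#' @export
run_exp1_pipeline <- function(dataset, config = pipeline_config()) {
  sched <- as.data.frame(dataset$schedule)
  subj_names <- names(dataset$subjects)
  if (is.null(subj_names)) stop("run_exp1_pipeline: dataset has no subjects",
                                call. = FALSE)
  exclusions <- data.frame(subject = character(0), onset_s = numeric(0),
                           reason = character(0))
  sn_proc <- list()
  sn_ep <- list(); scr_ep <- list()
  for (s in subj_names) {
    ch <- dataset$subjects[[s]]
    if (is.null(ch$scr)) stop("run_exp1_pipeline: missing 'scr' channel for ",
                              s, call. = FALSE)
    if (is.null(ch$sn) && is.null(ch$sn_raw)) {
      stop("run_exp1_pipeline: missing 'sn' channel for ", s, call. = FALSE)
    }
    scr_p <- preprocess_scr(ch$scr, config)
    sn_in <- if (!is.null(ch$sn)) ch$sn else ch$sn_raw
    sn_p <- preprocess_sn(sn_in, config)
    sn_proc[[s]] <- sn_p
    flags <- if (!is.null(config$clip_level)) {
      detect_clipping(sn_in, config$clip_level)
    } else data.frame()
    ev_s <- sched[sched$subject == s, , drop = FALSE]
    eps_scr <- extract_epochs(scr_p, ev_s, pre = config$epoch_pre,
                              post = config$epoch_post)
    eps_sn <- extract_epochs(sn_p, ev_s, pre = config$epoch_pre,
                             post = config$epoch_post)
    sk <- attr(eps_scr, "skipped")
    if (nrow(sk)) exclusions <- rbind(exclusions,
      data.frame(subject = s, onset_s = sk$onset_s, reason = sk$reason))
    keep <- rep(TRUE, length(eps_scr))
    if (nrow(flags)) {
      for (k in seq_along(eps_sn)) {
        if (epoch_overlaps_interval(eps_sn[[k]], flags)) {
          keep[k] <- FALSE
          exclusions <- rbind(exclusions,
            data.frame(subject = s, onset_s = eps_sn[[k]]$onset,
                       reason = "clipping in nerve signal"))
        }
      }
    }
    sn_ep <- c(sn_ep, eps_sn[keep])
    scr_ep <- c(scr_ep, lapply(eps_scr[keep], minimum_correct))
  }
  if (!length(scr_ep)) stop("run_exp1_pipeline: all epochs excluded", call. = FALSE)

  types <- unique(vapply(scr_ep, function(e) e$event_type, character(1)))
  avg_sn_can <- average_epochs(sn_ep, by = "event_type")
  avg_scr_can <- lapply(average_epochs(scr_ep, by = "event_type"), minimum_correct)
  avg_sn_sub <- average_epochs(sn_ep, by = "subject_event_type")
  avg_scr_sub <- lapply(average_epochs(scr_ep, by = "subject_event_type"),
                        minimum_correct)

  tf <- exp1_obs_transform(config)
  burst_fits <- lapply(avg_sn_can, fit_gaussian_burst, seed = config$seed)
  burst_fits_sub <- lapply(avg_sn_sub, fit_gaussian_burst, seed = config$seed)
  scrf_fits <- list(); scrf_fits_sub <- list()
  for (ty in types) {
    scrf_fits[[ty]] <- fit_scrf(epoch_as_ts(avg_sn_can[[ty]]),
                                avg_scr_can[[ty]], n_starts = config$n_starts,
                                seed = config$seed, substeps = config$substeps,
                                obs_transform = tf,
                                gain_intercept = config$gain_intercept)
  }
  for (g in names(avg_sn_sub)) {
    scrf_fits_sub[[g]] <- fit_scrf(epoch_as_ts(avg_sn_sub[[g]]),
                                   avg_scr_sub[[g]], n_starts = config$n_starts,
                                   seed = config$seed,
                                   substeps = config$substeps,
                                   obs_transform = tf,
                                   gain_intercept = config$gain_intercept)
  }

  # epoch predictions: convolve the whole preprocessed nerve recording with
  # the fitted response function (respecting carry-over between events),
  # filter like the data, then slice the event windows
  meta <- data.frame(
    subject = vapply(scr_ep, function(e) e$subject, character(1)),
    event_type = vapply(scr_ep, function(e) e$event_type, character(1)),
    repetition = vapply(scr_ep, function(e) e$index, integer(1))
  )
  pred_level <- function(fits, key_fun) {
    out <- vector("list", length(scr_ep))
    for (s in subj_names) {
      ev_s <- sched[sched$subject == s, , drop = FALSE]
      which_s <- which(meta$subject == s)
      for (ty in unique(meta$event_type[which_s])) {
        fit <- fits[[key_fun(s, ty)]]
        pred <- scrf_predict(fit$params, sn_proc[[s]],
                             ir_duration = config$pred_ir_duration)
        pred <- scr_filter_chain(pred, config)
        eps <- extract_epochs(pred, ev_s[ev_s$event_type == ty, , drop = FALSE],
                              pre = config$epoch_pre, post = config$epoch_post)
        idx <- which_s[meta$event_type[which_s] == ty]
        for (j in seq_along(idx)) out[[idx[j]]] <- eps[[j]]$values
      }
    }
    out
  }
  pred_can <- pred_level(scrf_fits, function(s, ty) ty)
  pred_sub <- pred_level(scrf_fits_sub, function(s, ty) paste(s, ty, sep = "."))
  obs <- lapply(scr_ep, function(e) e$values)

  gains_can <- estimate_gain(pred_can, scr_ep, mode = "per_epoch",
                             intercept = config$gain_intercept)
  gains_sub <- estimate_gain(pred_sub, scr_ep, mode = "per_epoch",
                             intercept = config$gain_intercept)

  apply_affine <- function(preds, tab) {
    lapply(seq_along(preds), function(k) {
      if (is.na(tab$gain[k])) return(rep(0, length(preds[[k]])))
      tab$gain[k] * preds[[k]] + tab$intercept[k]
    })
  }
  ev_results <- list(); partitions <- list()
  for (ty in types) {
    i <- which(meta$event_type == ty)
    p_can <- apply_affine(pred_can[i], gains_can[i, ])
    p_sub <- apply_affine(pred_sub[i], gains_sub[i, ])
    part <- variance_partition(obs[i], p_can, subject = p_sub,
                               subjects = meta$subject[i])
    # fixed gain per subject: one affine map across the subject's epochs
    sse_fix <- 0
    for (s in unique(meta$subject[i])) {
      j <- i[meta$subject[i] == s]
      ab <- affine_fixed(pred_can[j], obs[j], config$gain_intercept)
      sse_fix <- sse_fix + sum(vapply(j, function(k) {
        sum((obs[[k]] - ab["gain"] * pred_can[[k]] - ab["intercept"])^2)
      }, numeric(1)))
    }
    sst <- sum(vapply(obs[i], function(o) sum((o - mean(o))^2), numeric(1)))
    ev_results[[ty]] <- list(
      variable_gain_canonical = part$r2_canonical,
      variable_gain_subject = part$r2_subject,
      fixed_gain_canonical = 1 - sse_fix / sst
    )
    partitions[[ty]] <- part
  }

  trend <- tryCatch(gain_trend(gains_can), error = function(e) e)

  structure(list(
    kind = "exp1",
    n_epochs = length(scr_ep),
    n_excluded = nrow(exclusions),
    exclusions = exclusions,
    burst_fits = burst_fits,
    burst_fits_subject = burst_fits_sub,
    scrf_fits = scrf_fits,
    scrf_fits_subject = scrf_fits_sub,
    gains = gains_can,
    gains_subject_rf = gains_sub,
    explained_variance = ev_results,
    partition = partitions,
    gain_trend = trend,
    config = config,
    config_hash = config_hash(config),
    seed = config$seed
  ), class = "scr_report")
}

#' Run the intraneural-stimulation analysis pipeline
#'
#' End-to-end analysis of a stimulation-style dataset. Each constant-rate
#' epoch is sliced from the derivative-device channel and independently
#' reconstructed (mean-subtracted cumulative sum), band-pass filtered,
#' z-scored and minimum-corrected. Epochs are classified by mean
#' stimulation rate (>= 5 Hz epochs are excluded as beyond physiological
#' burst rates). The response function is fitted per epoch, per subject x
#' rate class, and pooled per rate class, with the model prediction passed
#' through the same device + reconstruction + filter chain before
#' comparison (see [pipeline_config()]'s `exp2_observation`). Explained
#' variance is partitioned across the three levels; each epoch's impulse
#' response is compared with a reference (when given); per-stimulation
#' gains are estimated and regressed on stimulation repetition.
#'
#' @param dataset An `scr_dataset` (style `"exp2"`) with per-subject
#'   `deriv` channels and an `epochs` table, or an equivalent list.
#' @param config A [pipeline_config].
#' @param reference_ir Optional reference impulse response ([scr_ts]).
#' @return A list of class `scr_report`.
#' @export
run_exp2_pipeline <- function(dataset, config = pipeline_config(),
                              reference_ir = NULL) {
  sched <- as.data.frame(dataset$schedule)
  spans <- dataset$epochs
  if (is.null(spans)) stop("run_exp2_pipeline: dataset has no epochs table",
                           call. = FALSE)
  for (s in names(dataset$subjects)) {
    if (is.null(dataset$subjects[[s]]$deriv)) {
      stop("run_exp2_pipeline: missing 'deriv' channel for ", s, call. = FALSE)
    }
  }

  classes <- classify_epochs_by_rate(sched, thresholds = config$rate_thresholds)
  classes$retained <- !classes$flagged & classes$class %in% c("low", "medium", "high")
  exclusions <- classes[!classes$retained,
                        c("epoch_id", "subject", "rate_hz", "class")]
  if (nrow(exclusions)) {
    exclusions$reason <- ifelse(classes$flagged[!classes$retained],
                                "fewer than 2 stimulations",
                                "stimulation rate at or above exclusion threshold")
  } else exclusions$reason <- character(0)

  ep_tab <- merge(classes[classes$retained, ], spans,
                  by = c("epoch_id", "subject"))
  ep_tab <- ep_tab[order(ep_tab$subject, ep_tab$t_start), , drop = FALSE]

  # z-scoring scale per subject (not per epoch, so gains stay comparable
  # across a subject's epochs): SD of the whole-recording reconstruction
  subj_scale <- vapply(names(dataset$subjects), function(s) {
    dv <- dataset$subjects[[s]]$deriv
    if (dv$rate > config$target_rate) dv <- downsample(dv, config$target_rate)
    r <- scr_filter_chain(reconstruct_scr_from_derivative(dv), config)
    stats::sd(r$values)
  }, numeric(1))

  # per-epoch preprocessing: slice, reconstruct, band-pass, scale,
  # minimum-correct; inputs are unit-area Gaussian trains on the same grid
  inputs <- list(); observeds <- list()
  for (k in seq_len(nrow(ep_tab))) {
    id <- ep_tab$epoch_id[k]
    s <- ep_tab$subject[k]
    dv <- slice_ts(dataset$subjects[[s]]$deriv, ep_tab$t_start[k],
                   ep_tab$t_end[k])
    if (dv$rate > config$target_rate) dv <- downsample(dv, config$target_rate)
    r <- reconstruct_scr_from_derivative(dv)
    r <- scr_filter_chain(r, config)
    vals <- r$values / max(subj_scale[[s]], .Machine$double.eps)
    vals <- vals - min(vals)
    on <- sched$onset_s[sched$epoch_id == id] - ep_tab$t_start[k]
    inputs[[id]] <- build_input_train(on, rate = config$target_rate,
                                      duration = length(vals) / config$target_rate,
                                      sigma_in = config$sigma_in)
    observeds[[id]] <- vals
  }

  tf <- exp2_obs_transform(config)
  fits_epoch <- lapply(ep_tab$epoch_id, function(id) {
    fit_scrf(inputs[[id]], observeds[[id]], n_starts = config$n_starts,
             seed = config$seed, substeps = config$substeps,
             obs_transform = tf, gain_intercept = config$gain_intercept)
  })
  names(fits_epoch) <- ep_tab$epoch_id

  # common models: per subject x rate class and pooled per rate class
  # (high-rate epochs stay out of common models and trend analyses)
  analysis_classes <- c("low", "medium")
  fits_subject <- list(); fits_canonical <- list()
  for (cl in analysis_classes) {
    i <- which(ep_tab$class == cl)
    if (!length(i)) next
    ids <- ep_tab$epoch_id[i]
    fits_canonical[[cl]] <- fit_scrf(inputs[ids], observeds[ids],
                                     n_starts = config$n_starts,
                                     seed = config$seed,
                                     substeps = config$substeps,
                                     obs_transform = tf,
                                     gain_intercept = config$gain_intercept)
    for (s in unique(ep_tab$subject[i])) {
      ids_s <- ids[ep_tab$subject[i] == s]
      fits_subject[[paste(s, cl, sep = ".")]] <-
        fit_scrf(inputs[ids_s], observeds[ids_s], n_starts = config$n_starts,
                 seed = config$seed, substeps = config$substeps,
                 obs_transform = tf, gain_intercept = config$gain_intercept)
    }
  }

  sim_pred <- function(params, id) {
    u <- inputs[[id]]
    p <- scrf_rk4_cpp(u$values, 1 / u$rate, params$theta1, params$theta2,
                      params$theta3, params$theta4, 1,
                      as.integer(config$substeps))
    tf(p)
  }
  predict_with <- function(fit, ids) {
    g <- rep_len(fit$gain, length(ids))
    b <- rep_len(fit$intercept %||% 0, length(ids))
    lapply(seq_along(ids), function(k) {
      g[k] * sim_pred(fit$params, ids[k]) + b[k]
    })
  }

  partitions <- list(); ev_results <- list()
  for (cl in analysis_classes) {
    i <- which(ep_tab$class == cl)
    if (!length(i)) next
    ids <- ep_tab$epoch_id[i]
    p_can <- predict_with(fits_canonical[[cl]], ids)
    p_sub <- list(); p_epo <- list()
    for (k in seq_along(ids)) {
      s <- ep_tab$subject[i][k]
      fs <- fits_subject[[paste(s, cl, sep = ".")]]
      ids_s <- ids[ep_tab$subject[i] == s]
      p_sub[[k]] <- predict_with(fs, ids_s)[[which(ids_s == ids[k])]]
      p_epo[[k]] <- predict_with(fits_epoch[[ids[k]]], ids[k])[[1]]
    }
    part <- variance_partition(observeds[ids], p_can, subject = p_sub,
                               epoch = p_epo, subjects = ep_tab$subject[i])
    ev_results[[cl]] <- list(
      per_epoch = part$r2_epoch,
      per_subject = part$r2_subject,
      pooled = part$r2_canonical,
      per_epoch_mean = mean(vapply(ids, function(id) fits_epoch[[id]]$r2,
                                   numeric(1)))
    )
    partitions[[cl]] <- part
  }

  ref_comparison <- NULL
  if (!is.null(reference_ir)) {
    dt <- 1 / config$target_rate
    ref_comparison <- do.call(rbind, lapply(seq_len(nrow(ep_tab)), function(k) {
      fit <- fits_epoch[[ep_tab$epoch_id[k]]]
      ir <- scrf_impulse_response(fit$params, dt = dt,
                                  duration = config$ir_duration)
      cmp <- compare_scrf_to_reference(ir, reference_ir)
      data.frame(epoch_id = ep_tab$epoch_id[k], subject = ep_tab$subject[k],
                 class = ep_tab$class[k], rate_hz = ep_tab$rate_hz[k],
                 r2 = cmp$r2, shift_s = cmp$shift_s)
    }))
  }

  # per-stimulation gains within each analysed epoch: OLS on the per-onset
  # unit responses (observation-transformed) of the epoch's own response
  # function, plus an intercept column when configured
  gain_rows <- list()
  for (k in seq_len(nrow(ep_tab))) {
    if (!(ep_tab$class[k] %in% analysis_classes)) next
    id <- ep_tab$epoch_id[k]
    fit <- fits_epoch[[id]]
    on <- sched$onset_s[sched$epoch_id == id] - ep_tab$t_start[k]
    rep_idx <- sched$repetition[sched$epoch_id == id]
    u <- inputs[[id]]
    X <- vapply(on, function(o) {
      uk <- build_input_train(o, rate = u$rate,
                              duration = length(u$values) / u$rate,
                              sigma_in = config$sigma_in)
      tf(scrf_rk4_cpp(uk$values, 1 / u$rate, fit$params$theta1,
                      fit$params$theta2, fit$params$theta3, fit$params$theta4,
                      1, as.integer(config$substeps)))
    }, numeric(length(u$values)))
    if (config$gain_intercept) X <- cbind(X, 1)
    ls <- stats::lm.fit(X, observeds[[id]])
    co <- ls$coefficients[seq_along(on)]
    gain_rows[[id]] <- data.frame(epoch_id = id, subject = ep_tab$subject[k],
                                  class = ep_tab$class[k],
                                  repetition = rep_idx,
                                  gain = unname(co))
  }
  gains <- do.call(rbind, gain_rows)
  trend <- tryCatch(gain_trend(gains), error = function(e) e)

  structure(list(
    kind = "exp2",
    epoch_table = ep_tab,
    n_epochs_input = nrow(classes),
    n_epochs_fitted = nrow(ep_tab),
    exclusions = exclusions,
    fits_epoch = fits_epoch,
    fits_subject = fits_subject,
    fits_canonical = fits_canonical,
    explained_variance = ev_results,
    partition = partitions,
    reference_comparison = ref_comparison,
    gains = gains,
    gain_trend = trend,
    config = config,
    config_hash = config_hash(config),
    seed = config$seed
  ), class = "scr_report")
}

#' @export
print.scr_report <- function(x, ...) {
  cat(sprintf("<scr_report> kind=%s\n", x$kind))
  if (x$kind == "exp1") {
    for (ty in names(x$explained_variance)) {
      ev <- x$explained_variance[[ty]]
      cat(sprintf("  %s: EV canonical %.1f%%, subject %.1f%%, fixed-gain %.1f%%\n",
                  ty, 100 * ev$variable_gain_canonical,
                  100 * ev$variable_gain_subject, 100 * ev$fixed_gain_canonical))
    }
  } else {
    for (cl in names(x$explained_variance)) {
      ev <- x$explained_variance[[cl]]
      cat(sprintf("  %s: EV per-epoch %.1f%%, per-subject %.1f%%, pooled %.1f%%\n",
                  cl, 100 * ev$per_epoch, 100 * ev$per_subject, 100 * ev$pooled))
    }
  }
  if (inherits(x$gain_trend, "gain_trend")) print(x$gain_trend)
  invisible(x)
}
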