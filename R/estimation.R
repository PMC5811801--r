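#' @title Fit result container
#' @description Common return value of the model fitters: estimated
#'   parameters, gain(s), explained-variance fraction, convergence
#'   information and the final objective value.
#' @name fit_result
NULL

new_fit_result <- function(params, gain, r2, converged, n_iter, objective,
                           extra = list()) {
  structure(c(list(params = params, gain = gain, r2 = r2,
                   converged = converged, n_iter = n_iter,
                   objective = objective), extra),
            class = "scr_fit")
}

#' @export
print.scr_fit <- function(x, ...) {
  cat(sprintf("<scr_fit> r2=%.4f converged=%s n_iter=%d objective=%.4g\n",
              x$r2, x$converged, x$n_iter, x$objective))
  if (inherits(x$params, "scrf_params")) {
    cat(sprintf("  theta = (%.4f, %.4f, %.4f, %.4f), gain = %s\n",
                x$params$theta1, x$params$theta2, x$params$theta3,
                x$params$theta4, paste(signif(x$gain, 4), collapse = ", ")))
  } else if (inherits(x$params, "burst_params")) {
    cat(sprintf("  A=%.4f mu=%.4f sigma=%.4f c=%.4f\n",
                x$params$A, x$params$mu, x$params$sigma, x$params$c))
  }
  invisible(x)
}

#' Fit the Gaussian burst model to an epoch
#'
#' Ordinary least squares fit of the Gaussian burst model to an averaged (or
#' single) sudomotor epoch using Nelder-Mead search, with a multi-start
#' strategy (jittered initial values under a fixed seed) to avoid shallow
#' local minima. The default initialization places `mu` at the epoch
#' argmax, uses `sigma` = 0.3 s, sets `c` to the epoch's 5th percentile and
#' derives `A` from the peak height.
#'
#' @param epoch An [scr_epoch] (time axis relative to the event onset) or an
#'   [scr_ts].
#' @param init Optional [burst_params] starting point.
#' @param n_starts Number of jittered starts (default 3).
#' @param seed Seed for the start jitter (default 1).
#' @param max_iter Maximum Nelder-Mead iterations per start.
#' @return A fit result (class `scr_fit`) with `params` a [burst_params].
#' @export
fit_gaussian_burst <- function(epoch, init = NULL, n_starts = 3, seed = 1,
                               max_iter = 2000) {
  x <- as_values(epoch)
  tt <- if (inherits(epoch, "scr_epoch")) epoch_time(epoch) else ts_time(epoch)
  stopifnot(length(x) == length(tt))

  sse <- function(par) {
    # par = (A, mu, log_sigma, c)
    sig <- exp(par[3])
    m <- par[1] / (sqrt(2 * pi) * sig) * exp(-(tt - par[2])^2 / (2 * sig^2)) + par[4]
    sum((m - x)^2)
  }

  if (is.null(init)) {
    c0 <- stats::quantile(x, 0.05, names = FALSE)
    mu0 <- tt[which.max(x)]
    sig0 <- 0.3
    A0 <- max(max(x) - c0, .Machine$double.eps) * sqrt(2 * pi) * sig0
    init <- burst_params(A = A0, mu = mu0, sigma = sig0, c = c0)
  }
  p0 <- c(init$A, init$mu, log(init$sigma), init$c)
  starts <- with_seed(seed, {
    lapply(seq_len(n_starts), function(k) {
      if (k == 1) return(p0)
      p0 + c(p0[1] * stats::rnorm(1, 0, 0.3),
             stats::rnorm(1, 0, 0.2),
             stats::rnorm(1, 0, 0.3),
             stats::rnorm(1, 0, 0.1 * max(stats::sd(x), 1e-12)))
    })
  })
  best <- NULL
  for (s in starts) {
    fit <- stats::optim(s, sse, method = "Nelder-Mead",
                        control = list(maxit = max_iter, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  pb <- best$par
  sst <- sum((x - mean(x))^2)
  r2 <- if (sst > 0) 1 - best$value / sst else 1
  new_fit_result(
    params = burst_params(A = pb[1], mu = pb[2], sigma = exp(pb[3]), c = pb[4]),
    gain = 1, r2 = r2, converged = best$convergence == 0,
    n_iter = unname(best$counts[1]), objective = best$value
  )
}

scrf_default_bounds <- function() {
  list(lower = c(1e-3, 1e-3, 1e-3, -5), upper = c(20, 20, 5, 5))
}

# simulate with gain 1 and return the profiled-gain residual sum of squares;
# with gain_intercept the gain is the slope of an affine profile and the
# intercept is returned alongside
scrf_objective <- function(thvec, inputs, observeds, fit_gain, priors,
                           substeps, obs_transform = NULL,
                           gain_intercept = FALSE) {
  sse <- 0
  gains <- numeric(length(inputs))
  icepts <- numeric(length(inputs))
  for (k in seq_along(inputs)) {
    u <- inputs[[k]]
    p <- scrf_rk4_cpp(u$values, 1 / u$rate, thvec[1], thvec[2], thvec[3],
                      thvec[4], 1, substeps)
    if (!is.null(obs_transform)) p <- obs_transform(p)
    o <- observeds[[k]]
    if (gain_intercept) {
      pc <- p - mean(p)
      oc <- o - mean(o)
      g <- if (fit_gain) {
        pp <- sum(pc * pc)
        if (pp > 0) sum(pc * oc) / pp else 0
      } else 1
      b <- mean(o) - g * mean(p)
      res <- o - g * p - b
    } else {
      g <- if (fit_gain) {
        pp <- sum(p * p)
        if (pp > 0) sum(p * o) / pp else 0
      } else 1
      b <- 0
      res <- o - g * p
    }
    gains[k] <- g
    icepts[k] <- b
    sse <- sse + sum(res^2)
  }
  if (!is.null(priors)) {
    sse <- sse + sum(((thvec - priors$mean) / priors$sd)^2)
  }
  attr(sse, "gains") <- gains
  attr(sse, "intercepts") <- icepts
  sse
}

#' Fit the ODE response function to observed data
#'
#' Estimates the SCRF coefficients (and, optionally, the response gain) by
#' penalized least squares: bounded multi-start nonlinear optimization
#' (L-BFGS-B, 5 jittered starts under a fixed seed) of the squared error
#' between the simulated ODE response to the given input and the observed
#' signal. The gain is profiled out analytically at each step (slope-only
#' OLS of observation on prediction), which both matches the definition of
#' the gain factor and removes one search dimension. Gaussian priors on the
#' coefficients, when given, add a quadratic penalty (MAP-style).
#'
#' When `input` and `observed` are lists of equal length, a single
#' coefficient set is fitted jointly across all segments with one profiled
#' gain per segment (the "common response function, variable gain" model);
#' the reported `r2` then pools sums of squares across segments, each taken
#' around its own mean.
#'
#' Because different coefficient vectors can produce near-identical impulse
#' responses, recovery should be judged on the impulse-response shape
#' (see [compare_scrf_to_reference()]), not on the raw coefficients.
#'
#' @param input Input signal ([scr_ts]) or list of inputs.
#' @param observed Observed response (numeric, [scr_ts] or [scr_epoch]) or
#'   list matching `input`.
#' @param priors Optional list with numeric `mean` and `sd` of length 4.
#' @param fit_gain Estimate the gain (default `TRUE`); if `FALSE` the gain
#'   is fixed at 1.
#' @param n_starts Number of optimization starts (default 5).
#' @param seed Seed for start jitter (default 1).
#' @param bounds List with `lower` and `upper` bounds on the four
#'   coefficients; defaults: `theta1`, `theta2` in (0, 20], `theta3` in
#'   (0, 5], `theta4` in [-5, 5].
#' @param substeps RK4 substeps per sample (default 10).
#' @param obs_transform Optional function (numeric vector in, numeric
#'   vector out) applied to the simulated response before residuals are
#'   formed — an observation model for data recorded through a known
#'   measurement chain (causal filters, a derivative-recording device).
#'   The default `NULL` compares the raw solution with the data.
#' @param gain_intercept Profile an affine map (slope + intercept) instead
#'   of a through-origin slope (default `FALSE`). Useful when the observed
#'   signal carries additive constants from z-scoring or minimum
#'   correction of filtered data.
#' @return A fit result (class `scr_fit`): `params` an [scrf_params],
#'   `gain` (scalar or per-segment vector), `intercept` likewise, `r2`,
#'   convergence flag, and a `per_start` table of objective values. A
#'   zero-variance observation is flagged `degenerate` and returns gain 0
#'   with `r2 = 1` by convention.
#' @export
fit_scrf <- function(input, observed, priors = NULL, fit_gain = TRUE,
                     n_starts = 5, seed = 1, bounds = scrf_default_bounds(),
                     substeps = 10L, obs_transform = NULL,
                     gain_intercept = FALSE) {
  inputs <- if (inherits(input, "scr_ts")) list(input) else input
  observeds <- if (is.list(observed) && !inherits(observed, c("scr_ts", "scr_epoch"))) {
    lapply(observed, as_values)
  } else {
    list(as_values(observed))
  }
  stopifnot(length(inputs) == length(observeds))
  for (k in seq_along(inputs)) {
    stopifnot(inherits(inputs[[k]], "scr_ts"))
    if (length(inputs[[k]]$values) != length(observeds[[k]])) {
      stop("fit_scrf: input and observed must share the grid", call. = FALSE)
    }
  }
  sst <- sum(vapply(observeds, function(o) sum((o - mean(o))^2), numeric(1)))
  if (sst == 0) {
    return(new_fit_result(params = scrf_params(1, 1, 0.5, 0),
                          gain = rep(0, length(inputs)), r2 = 1,
                          converged = TRUE, n_iter = 0L, objective = 0,
                          extra = list(degenerate = TRUE)))
  }
  substeps <- as.integer(substeps)
  obj <- function(th) as.numeric(scrf_objective(th, inputs, observeds, fit_gain,
                                                priors, substeps, obs_transform,
                                                gain_intercept))
  center <- c(2, 2.5, 0.3, 0)
  starts <- with_seed(seed, {
    lapply(seq_len(n_starts), function(k) {
      th <- if (k == 1) center else {
        c(center[1:3] * exp(stats::rnorm(3, 0, 0.5)),
          center[4] + stats::rnorm(1, 0, 0.5))
      }
      pmin(pmax(th, bounds$lower), bounds$upper)
    })
  })
  fits <- vector("list", n_starts)
  objs <- rep(NA_real_, n_starts)
  for (k in seq_len(n_starts)) {
    fits[[k]] <- tryCatch(
      stats::optim(starts[[k]], obj, method = "L-BFGS-B",
                   lower = bounds$lower, upper = bounds$upper,
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) e
    )
    if (!inherits(fits[[k]], "error")) objs[k] <- fits[[k]]$value
  }
  if (all(is.na(objs))) {
    msgs <- vapply(fits, function(f) conditionMessage(f), character(1))
    stop(paste0("fit_scrf: all starts failed:\n", paste(msgs, collapse = "\n")),
         call. = FALSE)
  }
  best <- fits[[which.min(objs)]]
  final <- scrf_objective(best$par, inputs, observeds, fit_gain, priors,
                          substeps, obs_transform, gain_intercept)
  gains <- attr(final, "gains")
  icepts <- attr(final, "intercepts")
  sse_data <- as.numeric(final)
  if (!is.null(priors)) {
    sse_data <- sse_data - sum(((best$par - priors$mean) / priors$sd)^2)
  }
  new_fit_result(
    params = scrf_params(best$par[1], best$par[2], best$par[3], best$par[4]),
    gain = if (length(gains) == 1) gains[[1]] else gains,
    r2 = 1 - sse_data / sst,
    converged = best$convergence == 0,
    n_iter = unname(best$counts[1]),
    objective = best$value,
    extra = list(intercept = if (length(icepts) == 1) icepts[[1]] else icepts,
                 per_start = data.frame(start = seq_len(n_starts),
                                        objective = objs))
  )
}

#' Estimate response gains by slope-only regression
#'
#' The gain factor between a predicted and an observed response is the
#' slope of an OLS regression through the origin,
#' `g = <p, o> / <p, p>` — computed per epoch (`mode = "per_epoch"`) or on
#' the concatenated epochs (`mode = "fixed"`, one gain for all). Gain
#' regression runs through the origin because minimum-corrected epochs have
#' no offset for an intercept to absorb; set `intercept = TRUE` for a
#' sensitivity analysis with a free intercept (the reported gain is then
#' the slope of that two-parameter fit).
#'
#' @param predicted A numeric vector / [scr_ts] / [scr_epoch], or a list of
#'   them (one per epoch).
#' @param observed Matching structure of observations.
#' @param mode `"per_epoch"` or `"fixed"`.
#' @param intercept Include an intercept (default `FALSE`).
#' @return For `"per_epoch"`: a `data.frame` with one row per epoch
#'   (columns `epoch`, `gain`, `intercept` (0 unless `intercept = TRUE`),
#'   `flagged`; metadata columns `subject`, `event_type`, `repetition`
#'   when the observations are [scr_epoch] objects). A zero-energy
#'   predictor yields `NA` gain and `flagged = TRUE`. For `"fixed"`: a
#'   single numeric gain.
#' @export
estimate_gain <- function(predicted, observed, mode = c("per_epoch", "fixed"),
                          intercept = FALSE) {
  mode <- match.arg(mode)
  wrap <- function(z) if (is.list(z) && !inherits(z, c("scr_ts", "scr_epoch"))) z else list(z)
  preds <- lapply(wrap(predicted), as_values)
  obs_raw <- wrap(observed)
  obs <- lapply(obs_raw, as_values)
  stopifnot(length(preds) == length(obs))
  for (k in seq_along(preds)) {
    if (length(preds[[k]]) != length(obs[[k]])) {
      stop("estimate_gain: predicted and observed lengths differ in epoch ", k,
           call. = FALSE)
    }
  }
  slope <- function(p, o) {
    if (intercept) {
      pp <- p - mean(p)
      den <- sum(pp^2)
      if (den == 0) return(c(NA_real_, NA_real_))
      g <- sum(pp * (o - mean(o))) / den
      c(g, mean(o) - g * mean(p))
    } else {
      den <- sum(p^2)
      if (den == 0) return(c(NA_real_, 0))
      c(sum(p * o) / den, 0)
    }
  }
  if (mode == "fixed") {
    return(slope(unlist(preds), unlist(obs))[1])
  }
  gb <- vapply(seq_along(preds), function(k) slope(preds[[k]], obs[[k]]),
               numeric(2))
  g <- gb[1, ]
  out <- data.frame(epoch = seq_along(g), gain = g, intercept = gb[2, ],
                    flagged = is.na(g))
  if (all(vapply(obs_raw, inherits, logical(1), "scr_epoch"))) {
    out$subject <- vapply(obs_raw, function(e) e$subject, character(1))
    out$event_type <- vapply(obs_raw, function(e) e$event_type, character(1))
    out$repetition <- vapply(obs_raw, function(e) e$index, integer(1))
  }
  out
}

#' Explained variance (coefficient of determination)
#'
#' `R^2 = 1 - sum((o - p)^2) / sum((o - mean(o))^2)`. May be negative for
#' predictors worse than the observation mean. A zero-variance observation
#' returns 1 by convention, with attribute `degenerate = TRUE`.
#'
#' @param predicted,observed Numeric vectors (or [scr_ts] / [scr_epoch]).
#' @return Numeric fraction (at most 1).
#' @export
explained_variance <- function(predicted, observed) {
  p <- as_values(predicted)
  o <- as_values(observed)
  stopifnot(length(p) == length(o))
  sst <- sum((o - mean(o))^2)
  if (sst == 0) return(structure(1, degenerate = TRUE))
  1 - sum((o - p)^2) / sst
}

#' Partition explained variance across response-function levels
#'
#' Splits the pooled variance of minimum-corrected epochs into the fraction
#' explained by a canonical response function common to all subjects, the
#' extra fraction explained by subject-specific response functions, the
#' extra fraction explained by epoch-specific response functions (when
#' available), and the unexplained residual. Pooled sums of squares are
#' used throughout, with each epoch's total sum of squares taken around its
#' own mean.
#'
#' A conservative fallback guards against overfitted higher levels: for any
#' subject whose subject-level predictions explain less pooled variance
#' than the canonical ones, the canonical predictions are substituted; the
#' same rule is applied per epoch at the epoch level. The increments are
#' therefore nonnegative and the fractions sum to one.
#'
#' @param observed List of numeric vectors (one per epoch, minimum-corrected).
#' @param canonical List of canonical-model predictions (gains applied).
#' @param subject Optional list of subject-level predictions.
#' @param epoch Optional list of epoch-level predictions.
#' @param subjects Character vector: subject label per epoch (required when
#'   `subject` is given).
#' @return A list of class `variance_partition` with fields `canonical`,
#'   `subject_extra`, `epoch_extra`, `residual` (fractions summing to 1;
#'   absent levels are `NA` and contribute nothing) plus the pooled
#'   `r2_canonical`, `r2_subject`, `r2_epoch`.
#' @export
variance_partition <- function(observed, canonical, subject = NULL,
                               epoch = NULL, subjects = NULL) {
  observed <- lapply(observed, as_values)
  canonical <- lapply(canonical, as_values)
  K <- length(observed)
  stopifnot(length(canonical) == K)
  sst_k <- vapply(observed, function(o) sum((o - mean(o))^2), numeric(1))
  sst <- sum(sst_k)
  res_can <- vapply(seq_len(K), function(k)
    sum((observed[[k]] - canonical[[k]])^2), numeric(1))
  r2_can <- 1 - sum(res_can) / sst

  res_sub <- NULL
  r2_sub <- NA_real_
  if (!is.null(subject)) {
    subject <- lapply(subject, as_values)
    stopifnot(length(subject) == K, !is.null(subjects), length(subjects) == K)
    res_sub <- vapply(seq_len(K), function(k)
      sum((observed[[k]] - subject[[k]])^2), numeric(1))
    for (s in unique(subjects)) {
      i <- subjects == s
      if (sum(res_sub[i]) > sum(res_can[i])) res_sub[i] <- res_can[i]
    }
    r2_sub <- 1 - sum(res_sub) / sst
  }

  res_epo <- NULL
  r2_epo <- NA_real_
  if (!is.null(epoch)) {
    epoch <- lapply(epoch, as_values)
    stopifnot(length(epoch) == K)
    base <- if (is.null(res_sub)) res_can else res_sub
    res_epo <- vapply(seq_len(K), function(k)
      sum((observed[[k]] - epoch[[k]])^2), numeric(1))
    res_epo <- pmin(res_epo, base)
    r2_epo <- 1 - sum(res_epo) / sst
  }

  top <- max(c(r2_can, r2_sub, r2_epo), na.rm = TRUE)
  structure(list(
    canonical = r2_can,
    subject_extra = if (is.na(r2_sub)) NA_real_ else r2_sub - r2_can,
    epoch_extra = if (is.na(r2_epo)) NA_real_ else
      r2_epo - if (is.na(r2_sub)) r2_can else r2_sub,
    residual = 1 - top,
    r2_canonical = r2_can, r2_subject = r2_sub, r2_epoch = r2_epo
  ), class = "variance_partition")
}

#' @export
print.variance_partition <- function(x, ...) {
  cat(sprintf("<variance_partition> canonical=%.3f subject_extra=%s epoch_extra=%s residual=%.3f\n",
              x$canonical,
              ifelse(is.na(x$subject_extra), "-", sprintf("%.3f", x$subject_extra)),
              ifelse(is.na(x$epoch_extra), "-", sprintf("%.3f", x$epoch_extra)),
              x$residual))
  invisible(x)
}

#' Compare an estimated response function to a reference
#'
#' Shared variance (R^2) between an estimated impulse response and a
#' reference impulse response: the reference is linearly interpolated onto
#' the estimated grid, optionally aligned by the integer-sample shift that
#' maximizes the cross-correlation (recording-site conduction delays shift
#' response functions in time without changing their shape), and the
#' estimated response is regressed onto it with slope and intercept.
#'
#' @param estimated_ir,reference_ir Impulse responses as [scr_ts] objects.
#' @param align Allow an integer-sample alignment shift (default `TRUE`).
#' @param max_shift_s Largest alignment shift in seconds (default 5).
#' @return List of class `scrf_comparison`: `r2`, `shift_s` (applied to the
#'   reference), `slope`, `intercept`.
#' @export
compare_scrf_to_reference <- function(estimated_ir, reference_ir,
                                      align = TRUE, max_shift_s = 5) {
  stopifnot(inherits(estimated_ir, "scr_ts"), inherits(reference_ir, "scr_ts"))
  e <- estimated_ir$values
  tt <- ts_time(estimated_ir) - estimated_ir$start
  r <- stats::approx(ts_time(reference_ir) - reference_ir$start,
                     reference_ir$values, xout = tt, rule = 2)$y
  if (length(e) != length(r)) {
    stop("compare_scrf_to_reference: grids do not match after resampling",
         call. = FALSE)
  }
  shift_ref <- function(r, k) {
    # positive k delays the reference
    if (k == 0) r
    else if (k > 0) c(rep(r[1], k), r[seq_len(length(r) - k)])
    else c(r[(-k + 1):length(r)], rep(r[length(r)], -k))
  }
  kmax <- if (align) round(max_shift_s * estimated_ir$rate) else 0L
  best <- c(k = 0, c2 = -Inf)
  for (k in seq(-kmax, kmax)) {
    rs <- shift_ref(r, k)
    if (stats::sd(rs) == 0 || stats::sd(e) == 0) next
    c2 <- stats::cor(e, rs)^2
    if (c2 > best["c2"]) best <- c(k = k, c2 = c2)
  }
  rs <- shift_ref(r, best[["k"]])
  fit <- stats::lm.fit(cbind(1, rs), e)
  r2 <- if (stats::sd(e) > 0) 1 - sum(fit$residuals^2) / sum((e - mean(e))^2) else 1
  structure(list(r2 = r2, shift_s = best[["k"]] / estimated_ir$rate,
                 slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1])),
            class = "scrf_comparison")
}

#' Linear trend of response gain over repetitions
#'
#' OLS regression of per-epoch gains on the repetition index with one
#' intercept per subject (fixed subject effects) — a deliberately simple
#' stand-in for a mixed-effects analysis of gain habituation or
#' sensitization.
#'
#' @param gains `data.frame` with columns `gain`, `repetition` and
#'   (optionally) `subject`. Rows with `NA` gain are dropped.
#' @return List of class `gain_trend`: `slope`, `se`, `t`, `p`, `df`.
#' @export
gain_trend <- function(gains) {
  stopifnot(is.data.frame(gains), all(c("gain", "repetition") %in% names(gains)))
  g <- gains[!is.na(gains$gain), , drop = FALSE]
  if (length(unique(g$repetition)) < 2L) {
    stop("gain_trend: need at least 2 distinct repetition values", call. = FALSE)
  }
  multi_subj <- "subject" %in% names(g) && length(unique(g$subject)) > 1L
  fit <- if (multi_subj) {
    stats::lm(gain ~ 0 + factor(subject) + repetition, data = g)
  } else {
    stats::lm(gain ~ repetition, data = g)
  }
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop(paste0("gain_trend: singular design; collinear columns: ",
                paste(names(cf)[is.na(cf)], collapse = ", ")), call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  row <- sm["repetition", ]
  structure(list(slope = unname(row[1]), se = unname(row[2]),
                 t = unname(row[3]), p = unname(row[4]),
                 df = fit$df.residual, n = nrow(g)),
            class = "gain_trend")
}

#' @export
print.gain_trend <- function(x, ...) {
  cat(sprintf("<gain_trend> slope=%.4g (SE %.3g), t(%d)=%.2f, p=%.3g\n",
              x$slope, x$se, x$df, x$t, x$p))
  invisible(x)
}

#' Classify stimulation epochs by mean rate
#'
#' Computes the mean stimulation rate of each epoch from its onsets,
#' `(n - 1) / (last - first)`, and assigns a rate class: `low` below
#' `thresholds["low"]`, `medium` between `thresholds["medium_lo"]` and
#' `thresholds["medium_hi"]`, `high` above `medium_hi`, and `excluded` at
#' or above `thresholds["exclude"]` (stimulation far beyond physiological
#' burst rates). Rates falling in the gap between `low` and `medium_lo`
#' are labelled `unclassified`. Epochs with fewer than 2 onsets get `NA`
#' rate and are flagged.
#'
#' @param events An [event_schedule] with an `epoch_id` column.
#' @param thresholds Named numeric vector with entries `low`, `medium_lo`,
#'   `medium_hi`, `exclude` (defaults 0.12, 0.19, 0.6, 5 Hz).
#' @return `data.frame` with one row per epoch: `epoch_id`, `subject`,
#'   `n_events`, `rate_hz`, `class`, `flagged`.
#' @export
classify_epochs_by_rate <- function(events,
                                    thresholds = c(low = 0.12, medium_lo = 0.19,
                                                   medium_hi = 0.6, exclude = 5)) {
  stopifnot(is.data.frame(events), "epoch_id" %in% names(events))
  ev <- as.data.frame(events)
  ids <- unique(ev$epoch_id)
  out <- lapply(ids, function(id) {
    e <- ev[ev$epoch_id == id, , drop = FALSE]
    n <- nrow(e)
    rate <- if (n >= 2) (n - 1) / (max(e$onset_s) - min(e$onset_s)) else NA_real_
    cls <- if (is.na(rate)) {
      NA_character_
    } else if (rate >= thresholds[["exclude"]]) {
      "excluded"
    } else if (rate > thresholds[["medium_hi"]]) {
      "high"
    } else if (rate >= thresholds[["medium_lo"]]) {
      "medium"
    } else if (rate < thresholds[["low"]]) {
      "low"
    } else {
      "unclassified"
    }
    data.frame(epoch_id = id, subject = e$subject[1], n_events = n,
               rate_hz = rate, class = cls, flagged = is.na(rate),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
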