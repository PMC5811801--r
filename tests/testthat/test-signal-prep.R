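test_that("time-series and schedule containers enforce their invariants", {
  expect_error(scr_ts(numeric(0), 10), "at least one")
  expect_error(scr_ts(c(1, NA), 10), "finite")
  expect_error(scr_ts(1:5, -1), "positive")
  ts <- scr_ts(1:5, rate = 10, start = 2)
  expect_equal(ts_time(ts), 2 + (0:4) / 10)
  expect_error(event_schedule(c(1, 1)), "strictly increasing")
  ev <- event_schedule(c(5, 40, 80), event_type = c("a", "a", "b"))
  expect_equal(ev$repetition, c(1L, 2L, 1L))
  expect_error(scr_epoch(1:10, 10, 0), "expected 300 samples")
})

test_that("Butterworth filtering rejects DC and matches closed-form magnitudes", {
  # DC rejection of the high-pass: a constant decays toward zero
  const <- scr_ts(rep(1, 5000), rate = 10)
  hp <- butter_filter(const, low_cut = 0.0159)
  expect_lt(abs(hp$values[5000]), 1e-3)

  # steady-state amplitude at the low-pass cutoff ~ 1/sqrt(2)
  rate <- 100
  tt <- seq(0, 60, by = 1 / rate)
  sine <- scr_ts(sin(2 * pi * 5 * tt), rate = rate)
  lp <- butter_filter(sine, high_cut = 5)
  amp <- max(abs(lp$values[(length(tt) - 400):length(tt)]))
  expect_lt(abs(amp - 1 / sqrt(2)), 0.05 / sqrt(2))

  # 0.5 Hz through the 0.0159-5 Hz band-pass: closed-form cascade magnitude
  sine2 <- scr_ts(sin(2 * pi * 0.5 * tt), rate = rate)
  bp <- butter_filter(sine2, low_cut = 0.0159, high_cut = 5)
  amp2 <- max(abs(bp$values[(length(tt) - 400):length(tt)]))
  h_analog <- (0.5 / sqrt(0.5^2 + 0.0159^2)) * (1 / sqrt(1 + (0.5 / 5)^2))
  expect_lt(abs(amp2 - h_analog) / h_analog, 0.05)

  expect_error(butter_filter(const, high_cut = 6), "Nyquist")
  expect_error(butter_filter(const), "at least one")
})

test_that("equiripple FIR band-pass meets its pass- and stop-band contract", {
  h <- scrlti:::fir_nerve_coefs(10000)
  H <- function(f) abs(sum(h * exp(-2i * pi * f * (0:398) / 10000)))
  expect_lt(abs(20 * log10(H(1000))), 1)                   # pass band +-1 dB
  expect_lt(20 * log10(H(50) / H(1000)), -20)              # stop band
  zero <- scr_ts(rep(0, 2000), rate = 10000)
  expect_equal(fir_bandpass_nerve(zero)$values, rep(0, 2000))
  # delay compensation: a burst stays centred
  tt <- (0:9999) / 10000
  x <- sin(2 * pi * 1000 * tt) * exp(-(tt - 0.5)^2 / (2 * 0.01^2))
  y <- fir_bandpass_nerve(scr_ts(x, rate = 10000))
  expect_equal(length(y$values), length(x))
  expect_lt(abs(which.max(abs(y$values)) - which.max(abs(x))), 25)
  expect_error(fir_bandpass_nerve(scr_ts(1:100, rate = 1000)), "too low")
})

test_that("z-scoring is exact, idempotent and affine-invariant", {
  x <- scr_ts(rnorm(500, 3, 7), rate = 10)
  z <- zscore(x)
  expect_lt(abs(mean(z$values)), 1e-10)
  expect_lt(abs(sd(z$values) - 1), 1e-10)
  expect_equal(zscore(z)$values, z$values, tolerance = 1e-10)
  aff <- scr_ts(2.5 * x$values + 4, rate = 10)
  expect_equal(zscore(aff)$values, z$values, tolerance = 1e-10)
  expect_error(zscore(scr_ts(rep(1, 10), 10)), "zero-variance")
})

test_that("rectified leaky integration follows its recurrence", {
  zero <- scr_ts(rep(0, 100), rate = 10)
  expect_equal(rectified_leaky_integrate(zero)$values, rep(0, 100))
  # single unit sample then zeros: successive ratio = exp(-dt/tau)
  pulse <- scr_ts(c(1, rep(0, 99)), rate = 10)
  y <- rectified_leaky_integrate(pulse, tau = 0.1)$values
  expect_equal(y[3] / y[2], exp(-1), tolerance = 1e-12)
  # constant input converges to the constant (unit envelope gain)
  const <- rectified_leaky_integrate(scr_ts(rep(-2, 400), rate = 10),
                                     tau = 0.1)
  expect_equal(const$values[400], 2, tolerance = 1e-6)
  expect_true(all(const$values >= 0))
})

test_that("decimation keeps the first sample of each block", {
  ramp <- scr_ts(0:99 / 100, rate = 100)
  d <- downsample(ramp, 10)
  expect_equal(d$rate, 10)
  expect_equal(d$values, ramp$values[seq(1, 100, by = 10)])
  expect_equal(downsample(ramp, 100)$values, ramp$values)
  expect_error(downsample(ramp, 30), "integer multiple")
})

test_that("piecewise detrending removes lines per window", {
  line <- scr_ts(3 + 0.2 * (0:239), rate = 10)
  expect_lt(max(abs(piecewise_detrend(line, 5)$values)), 1e-9)
  set.seed(1)
  noise <- scr_ts(rnorm(240), rate = 10)
  out <- piecewise_detrend(noise, 5)$values
  for (s in seq(1, 240, by = 50)) {
    expect_lt(abs(mean(out[s:min(s + 49, 240)])), 1e-9)
  }
  # line + fast sinusoid (period << window): amplitude error < 5%, and the
  # result equals an independently coded per-window OLS oracle
  tt <- (0:499) / 10
  x <- scr_ts(2 + 0.3 * tt + sin(2 * pi * 2 * tt), rate = 10)
  rec <- piecewise_detrend(x, 5)$values
  expect_lt(abs(max(rec[100:400]) - 1), 0.05)
  oracle <- unlist(lapply(seq(1, 500, by = 50), function(s) {
    idx <- s:min(s + 49, 500)
    stats::residuals(stats::lm(x$values[idx] ~ idx))
  }))
  expect_equal(rec, unname(oracle), tolerance = 1e-10)
  expect_error(piecewise_detrend(scr_ts(1:10, 10), window = 0.1), "window")
})

test_that("cumulative-sum reconstruction inverts a first difference", {
  alt <- scr_ts(rep(c(1, -1), 50), rate = 10)
  r <- reconstruct_scr_from_derivative(alt)
  expect_equal(r$values, rep(c(1, 0), 50))
  expect_lt(abs(r$values[100]), 1e-12)  # last sample returns to zero
  expect_equal(reconstruct_scr_from_derivative(scr_ts(rep(2, 30), 10))$values,
               rep(0, 30))
  # first difference of a known response, re-integrated (the response must
  # decay within the record, else the mean-subtraction leak dominates)
  th <- canonical_params()$theta$low_rate
  u <- build_input_train(5, rate = 10, duration = 60)
  x <- scrf_simulate(th, u, gain = -1)
  d <- scr_ts(c(0, diff(x$values)), rate = 10)
  rec <- reconstruct_scr_from_derivative(d)
  expect_gt(cor(rec$values, x$values), 0.99)
})

test_that("epoch extraction slices half-open windows and skips the boundary", {
  ramp <- scr_ts(0:399 / 10, rate = 10)   # value == time
  ev <- event_schedule(c(10, 38), subject = "s01")
  expect_warning(eps <- extract_epochs(ramp, ev), "out of bounds")
  expect_length(eps, 1)
  expect_equal(length(eps[[1]]$values), 300)
  expect_equal(eps[[1]]$values, seq(5, 34.9, by = 0.1))
  expect_equal(nrow(attr(eps, "skipped")), 1)
  # time invariance: shifting all onsets by k samples shifts the slices
  set.seed(2)
  sig <- scr_ts(rnorm(800), rate = 10)
  e1 <- extract_epochs(sig, event_schedule(20), pre = 5, post = 25)
  e2 <- extract_epochs(sig, event_schedule(20 + 1.3), pre = 5, post = 25)
  expect_equal(e2[[1]]$values[1:287], e1[[1]]$values[14:300])
})

test_that("minimum correction and epoch averaging behave as stated", {
  e <- scr_epoch(seq(-0.3, by = 0.01, length.out = 300), 10, 10)
  mc <- minimum_correct(e)
  expect_equal(min(mc$values), 0)
  expect_equal(diff(mc$values), diff(e$values))
  expect_equal(minimum_correct(mc)$values, mc$values)
  expect_equal(minimum_correct(scr_epoch(rep(4, 300), 10, 0))$values,
               rep(0, 300))

  mk <- function(v, subj = "s01", ty = "a") scr_epoch(v, 10, 0,
                                                      event_type = ty,
                                                      subject = subj)
  x <- rnorm(300)
  avg <- average_epochs(list(mk(x), mk(x)), by = "event_type")
  expect_equal(avg[["a"]]$values, x)
  avg0 <- average_epochs(list(mk(x), mk(-x)), by = "event_type")
  expect_equal(avg0[["a"]]$values, rep(0, 300), tolerance = 1e-12)
  # averaging noisy copies concentrates around the template (CLT bound)
  set.seed(3)
  tmpl <- sin(seq(0, 3 * pi, length.out = 300))
  noisy <- lapply(1:10, function(i) mk(tmpl + rnorm(300)))
  avgn <- average_epochs(noisy, by = "event_type")[["a"]]
  expect_lt(max(abs(avgn$values - tmpl)), 4 / sqrt(10))
})

test_that("clipping detection flags saturated runs", {
  ts <- scr_ts(c(rep(0.1, 10), rep(2, 5), rep(0.1, 10), 2, 2, rep(0.1, 5),
                 rep(-2, 4)), rate = 10)
  flags <- detect_clipping(ts, level = 2)
  expect_equal(nrow(flags), 2)          # the 2-sample run is not flagged
  expect_equal(flags$start_idx, c(11, 33))
  expect_equal(flags$end_idx, c(15, 36))
  expect_equal(nrow(detect_clipping(scr_ts(rnorm(100) / 10, 10), 2)), 0)
  ep <- scr_epoch(rep(0, 300), 10, onset = 6)
  expect_true(epoch_overlaps_interval(ep, flags))
  ep2 <- scr_epoch(rep(0, 300), 10, onset = 200)
  expect_false(epoch_overlaps_interval(ep2, flags))
})
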