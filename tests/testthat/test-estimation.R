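canon <- canonical_params()

test_that("the Gaussian burst fitter recovers generating parameters", {
  po <- canon$burst$oddball
  tt <- seq(-5, 25, by = 0.1)[1:300]
  ep <- scr_epoch(gaussian_burst(tt, po)$values, 10, 0,
                  event_type = "oddball")
  f <- fit_gaussian_burst(ep)
  expect_true(f$converged)
  expect_gt(f$r2, 0.9999)
  expect_lt(abs(f$params$A - po$A) / po$A, 1e-3)
  expect_lt(abs(f$params$mu - po$mu) / po$mu, 1e-3)
  expect_lt(abs(f$params$sigma - po$sigma) / po$sigma, 1e-3)
  # degenerate constant epoch: flat baseline, no burst
  fc <- fit_gaussian_burst(scr_epoch(rep(0.7, 300), 10, 0))
  expect_lt(abs(fc$params$A), 1e-6)
  expect_equal(fc$params$c, 0.7, tolerance = 1e-6)
  # noisy recovery at 10% of peak, fixed seed
  set.seed(31)
  peak <- po$A / (sqrt(2 * pi) * po$sigma)
  noisy <- scr_epoch(gaussian_burst(tt, po)$values + rnorm(300, 0, 0.1 * peak),
                     10, 0)
  fn <- fit_gaussian_burst(noisy)
  expect_lt(abs(fn$params$mu - po$mu), 0.1)
  expect_lt(abs(fn$params$sigma - po$sigma) / po$sigma, 0.2)
})

test_that("the response-function fitter recovers shape from noiseless data", {
  th <- canon$theta$low_rate
  set.seed(8)
  onsets <- 5 + 10 * (0:9) + runif(10, -0.3, 0.3)
  u <- build_input_train(onsets, rate = 10, duration = 130)
  x <- scrf_simulate(th, u, gain = 1)
  f <- fit_scrf(u, x$values)
  expect_gt(f$r2, 0.999)
  expect_equal(f$gain, 1, tolerance = 0.05)
  ir_t <- scrf_impulse_response(th, duration = 30)
  ir_f <- scrf_impulse_response(f$params, duration = 30)
  expect_gt(cor(ir_t$values, ir_f$values)^2, 0.99)
  # a zero-variance observation must not crash and is flagged
  f0 <- fit_scrf(u, rep(0, length(u$values)))
  expect_true(isTRUE(f0$degenerate))
  expect_equal(f0$r2, 1)
  expect_equal(unname(f0$gain[1]), 0)
})

test_that("the response-function fitter tolerates 20% observation noise", {
  th <- canon$theta$low_rate
  set.seed(9)
  u <- build_input_train(5 + 10 * (0:9), rate = 10, duration = 130)
  clean <- scrf_simulate(th, u, gain = 1)$values
  noisy <- clean + rnorm(length(clean), 0, 0.2 * sd(clean))
  f <- fit_scrf(u, noisy)
  expect_gt(f$r2, 0.9)
})

test_that("joint fits share coefficients with per-segment gains", {
  th <- canon$theta$low_rate
  u1 <- build_input_train(c(4, 14, 24), rate = 10, duration = 60)
  u2 <- build_input_train(c(6, 18), rate = 10, duration = 60)
  o1 <- scrf_simulate(th, u1, gain = 2)$values
  o2 <- scrf_simulate(th, u2, gain = 0.5)$values
  f <- fit_scrf(list(u1, u2), list(o1, o2))
  expect_length(f$gain, 2)
  expect_equal(f$gain, c(2, 0.5), tolerance = 0.05)
  expect_gt(f$r2, 0.999)
})

test_that("gain estimation matches its closed form and is scale-equivariant", {
  set.seed(4)
  p <- rnorm(200)
  expect_equal(estimate_gain(p, 3 * p, mode = "fixed"), 3)
  o_orth <- p - p  # orthogonal trivially: zero vector
  expect_equal(estimate_gain(p, o_orth, mode = "fixed"), 0)
  o <- rnorm(200)
  expect_equal(estimate_gain(p, o, mode = "fixed"), sum(p * o) / sum(p * p))
  tab <- estimate_gain(list(p, 2 * p), list(o, o), mode = "per_epoch")
  expect_equal(tab$gain[1], sum(p * o) / sum(p * p))
  # scaling the observation scales every gain exactly
  tab2 <- estimate_gain(list(p, 2 * p), list(5 * o, 5 * o), mode = "per_epoch")
  expect_equal(tab2$gain, 5 * tab$gain)
  # zero-energy predictor flagged
  tab3 <- estimate_gain(list(rep(0, 10)), list(rnorm(10)), mode = "per_epoch")
  expect_true(tab3$flagged[1])
  expect_true(is.na(tab3$gain[1]))
})

test_that("explained variance equals its brute-force definition", {
  set.seed(5)
  o <- rnorm(100)
  p <- o + rnorm(100, 0, 0.5)
  expect_equal(explained_variance(o, o), 1)
  expect_equal(explained_variance(rep(mean(o), 100), o), 0, tolerance = 1e-12)
  expect_equal(explained_variance(p, o),
               1 - sum((o - p)^2) / sum((o - mean(o))^2))
  # can be negative for a bad predictor; degenerate observation flagged
  expect_lt(explained_variance(-o, o), 0)
  dg <- explained_variance(rnorm(10), rep(1, 10))
  expect_true(attr(dg, "degenerate"))
  # relation to squared correlation holds only for the OLS-fitted affine map
  g <- sum((p - mean(p)) * (o - mean(o))) / sum((p - mean(p))^2)
  b <- mean(o) - g * mean(p)
  expect_equal(explained_variance(g * p + b, o), cor(p, o)^2,
               tolerance = 1e-12)
})

test_that("variance partitioning is conservative, nonnegative and sums to 1", {
  set.seed(6)
  tmpl <- sin(seq(0, 3 * pi, length.out = 120))
  obs <- list(); can <- list(); sub <- list(); epo <- list()
  subjects <- rep(c("a", "b"), each = 3)
  for (k in 1:6) {
    o <- tmpl * (1 + 0.2 * k) + rnorm(120, 0, 0.3)
    obs[[k]] <- o
    can[[k]] <- tmpl * (1 + 0.2 * k)
    sub[[k]] <- can[[k]] + 0.05 * rnorm(120)   # no better than canonical
    epo[[k]] <- o                              # perfect epoch-level fit
  }
  vp <- variance_partition(obs, can, subject = sub, epoch = epo,
                           subjects = subjects)
  expect_gte(vp$subject_extra, 0)
  expect_gte(vp$epoch_extra, 0)
  expect_equal(vp$canonical + vp$subject_extra + vp$epoch_extra + vp$residual,
               1, tolerance = 1e-9)
  expect_gte(vp$r2_epoch, vp$r2_subject)
  expect_gte(vp$r2_subject, vp$r2_canonical)
  expect_equal(vp$r2_epoch, 1)   # epoch predictions reproduce the data
  # genuinely better subject-level predictions earn subject_extra > 0
  sub2 <- obs
  vp2 <- variance_partition(obs, can, subject = sub2, subjects = subjects)
  expect_gt(vp2$subject_extra, 0)
  expect_equal(vp2$residual, 0, tolerance = 1e-12)
})

test_that("reference comparison is affine-invariant and shift-aware", {
  th <- canon$theta$low_rate
  ir <- scrf_impulse_response(th, duration = 30)
  self <- compare_scrf_to_reference(ir, ir)
  expect_equal(self$r2, 1, tolerance = 1e-12)
  expect_equal(self$shift_s, 0)
  aff <- scr_ts(2.4 * ir$values - 0.7, rate = 10)
  expect_equal(compare_scrf_to_reference(aff, ir)$r2, 1, tolerance = 1e-12)
  # a time-shifted copy is recovered via the alignment search
  shifted <- scr_ts(c(rep(0, 13), ir$values[1:288]), rate = 10)
  cmp <- compare_scrf_to_reference(shifted, ir)
  expect_gt(cmp$r2, 0.999)
  expect_equal(cmp$shift_s, 1.3, tolerance = 1e-9)
  # white noise shares essentially no variance with the reference
  set.seed(7)
  noise <- scr_ts(rnorm(301), rate = 10)
  expect_lt(compare_scrf_to_reference(noise, ir, align = FALSE)$r2, 0.05)
})

test_that("gain-trend regression recovers slopes with subject intercepts", {
  g <- expand.grid(repetition = 1:10, subject = c("a", "b", "c"))
  g$gain <- 0.1 * g$repetition + c(a = 1, b = 2, c = 3)[g$subject]
  tr <- suppressWarnings(gain_trend(g))   # noiseless fit is exact
  expect_equal(tr$slope, 0.1, tolerance = 1e-9)
  expect_lt(tr$se, 1e-9)
  g0 <- data.frame(gain = rep(2, 10), repetition = 1:10, subject = "a")
  expect_equal(suppressWarnings(gain_trend(g0))$slope, 0, tolerance = 1e-12)
  # stochastic recovery: slope -0.05, noise SD 0.1, n = 200
  set.seed(10)
  gs <- expand.grid(repetition = 1:50, subject = c("a", "b", "c", "d"))
  gs$gain <- 1 - 0.05 * gs$repetition + rnorm(200, 0, 0.1)
  trs <- gain_trend(gs)
  expect_lt(abs(trs$slope - (-0.05)), 2 * trs$se)
  expect_error(gain_trend(data.frame(gain = 1:3, repetition = 1,
                                     subject = "a")), "distinct repetition")
})

test_that("epochs are classified by mean stimulation rate", {
  mk <- function(onsets, id) data.frame(onset_s = onsets, event_type = "stim",
                                        subject = "s01",
                                        repetition = seq_along(onsets),
                                        epoch_id = id)
  ev <- rbind(mk(seq(0, 90, 10), "slow"), mk(seq(100, 120, 2), "mid"),
              mk(seq(130, 131.5, 0.1), "vfast"), mk(seq(140, 145, 1), "fast"),
              mk(150, "single"), mk(c(160, 166.6), "gap"))
  cls <- classify_epochs_by_rate(ev)
  get <- function(id, col) cls[cls$epoch_id == id, col]
  expect_equal(get("slow", "class"), "low")
  expect_equal(get("slow", "rate_hz"), 0.1)
  expect_equal(get("mid", "class"), "medium")
  expect_equal(get("vfast", "class"), "excluded")
  expect_equal(get("fast", "class"), "high")
  expect_true(get("single", "flagged"))
  expect_equal(get("gap", "class"), "unclassified")  # 0.15 Hz gap
})
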