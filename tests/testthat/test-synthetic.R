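canon <- canonical_params()

test_that("schedules honour gaps, rates and determinism", {
  cfg <- synth_config("exp1", n_subjects = 2,
                      events = list(aversive = 20), seed = 3)
  sched <- make_schedule(cfg)
  for (s in unique(sched$subject)) {
    gaps <- diff(sched$onset_s[sched$subject == s])
    expect_true(all(gaps >= 30))
  }
  expect_equal(sum(sched$subject == "s01"), 20)

  cfg2 <- synth_config("exp2", rates_by_subject = list(s01 = 0.1),
                       seed = 3)
  sched2 <- make_schedule(cfg2)
  expect_equal(nrow(sched2), 39)  # low-rate epochs hold ~39 events
  rate <- (nrow(sched2) - 1) / diff(range(sched2$onset_s))
  expect_lt(abs(rate - 0.1) / 0.1, 0.05)

  again <- make_schedule(cfg2)
  expect_identical(sched2, again)
})

test_that("the nerve generator composes bursts, baseline and drift", {
  ev <- event_schedule(c(40, 80), event_type = "aversive")
  sn <- synth_sn(ev, canon$burst["aversive"], noise_sd = 0, rate = 10,
                 duration = 120)
  pa <- canon$burst$aversive
  tt <- (0:1199) / 10
  expected <- pa$A * dnorm(tt, 40 + pa$mu, pa$sigma) +
    pa$A * dnorm(tt, 80 + pa$mu, pa$sigma) + pa$c
  expect_equal(sn$values, expected, tolerance = 1e-12)
})

test_that("the conductance generator equals direct simulation for unit gains", {
  ev <- event_schedule(c(10, 45), event_type = "stimulation")
  th <- canon$theta$low_rate
  scr <- synth_scr(ev, th, gains = 1, areas = 1, sigma_in = 0.3,
                   noise_sd = 0, rate = 10, duration = 90)
  u <- build_input_train(c(10, 45), rate = 10, duration = 90, sigma_in = 0.3)
  direct <- scrf_simulate(th, u, gain = -1)
  expect_equal(scr$values, direct$values, tolerance = 1e-9)
})

test_that("measurement noise sets the analytic explained-variance ceiling", {
  ev <- event_schedule(seq(10, 380, by = 12), event_type = "stimulation")
  th <- canon$theta$low_rate
  set.seed(12)
  scr <- synth_scr(ev, th, gains = 1, noise_sd = 0.2, rate = 10,
                   duration = 420)
  clean <- attr(scr, "clean")
  ev_frac <- explained_variance(clean, scr$values)
  expect_equal(ev_frac, 1 / (1 + 0.04), tolerance = 0.01)
})

test_that("gain depletion follows its recurrence and recovery limits", {
  expect_equal(apply_depletion(rep(2, 5), seq(0, 40, 10), 0, 20), rep(2, 5))
  # onsets far apart relative to recovery: gains essentially unchanged
  far <- apply_depletion(rep(1, 4), c(0, 200, 400, 600), 0.5, 20)
  expect_equal(far, rep(1, 4), tolerance = 1e-4)
  # 1.5 Hz train: strictly decreasing effective gains, matching the
  # step-by-step recurrence
  onsets <- seq(0, by = 1 / 1.5, length.out = 6)
  eff <- apply_depletion(rep(1, 6), onsets, 0.3, 20)
  expect_true(all(diff(eff) < 0))
  s <- 1; manual <- numeric(6)
  for (k in 1:6) {
    if (k > 1) s <- 1 - (1 - s) * exp(-(onsets[k] - onsets[k - 1]) / 20)
    manual[k] <- s
    s <- s * (1 - 0.3)
  }
  expect_equal(eff, manual, tolerance = 1e-12)
})

test_that("the derivative-recorder emulation is linear and derivative-like", {
  # a constant is rejected once the coupling transients die away
  const <- scr_ts(rep(3, 600), rate = 10)
  out <- emulate_derivative_recorder(const)
  expect_lt(max(abs(out$values[500:600])), 1e-6)
  th <- canon$theta$low_rate
  x <- synth_scr(event_schedule(c(10, 40)), th, rate = 10, duration = 80)
  y1 <- emulate_derivative_recorder(x)
  y2 <- emulate_derivative_recorder(scr_ts(2 * x$values, rate = 10))
  expect_equal(y2$values, 2 * y1$values, tolerance = 1e-12)
  # in the conductance band the AC-coupled output tracks the derivative
  # (imperfectly: the finite rise and decay constants shape it)
  d <- c(0, diff(x$values)) * 10
  expect_gt(cor(y1$values[50:800], d[50:800]), 0.8)
})

test_that("generated datasets are reproducible and analysis-ready", {
  cfg <- tiny_exp1_cfg(seed = 21)
  ds <- generate_dataset(cfg)
  ds2 <- generate_dataset(cfg)
  expect_identical(dataset_hash(ds), dataset_hash(ds2))
  # every scheduled event admits a full epoch window
  for (s in names(ds$subjects)) {
    ev_s <- as.data.frame(ds$schedule)
    ev_s <- ev_s[ev_s$subject == s, ]
    eps <- extract_epochs(ds$subjects[[s]]$scr, ev_s)
    expect_length(eps, nrow(ev_s))
  }
  # truth gains recorded per onset
  expect_equal(nrow(ds$truth$gains), nrow(as.data.frame(ds$schedule)))

  cfg2 <- tiny_exp2_cfg(seed = 22,
                        rates = list(s01 = c(0.1, 0.2, 0.5, 1, 1.5)),
                        n_events = 6)
  ds2b <- generate_dataset(cfg2)
  cls <- classify_epochs_by_rate(ds2b$schedule)
  expect_equal(cls$class[order(cls$epoch_id)],
               c("low", "medium", "medium", "high", "high"))
})

test_that("raw nerve emulation carries band-limited bursts", {
  ev <- event_schedule(0.5, event_type = "aversive")
  set.seed(13)
  raw <- synth_raw_nerve(ev, canon$burst$aversive, rate = 10000,
                         duration = 4)
  expect_equal(length(raw$values), 40000)
  env <- rectified_leaky_integrate(zscore(fir_bandpass_nerve(raw)), 0.1)
  # the envelope peaks near onset + burst latency
  pk <- (which.max(env$values) - 1) / 10000
  expect_lt(abs(pk - (0.5 + canon$burst$aversive$mu)), 0.3)
})
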