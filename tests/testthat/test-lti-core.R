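canon <- canonical_params()

test_that("the Gaussian burst model evaluates its closed form", {
  p0 <- burst_params(A = 0, mu = 1, sigma = 0.3, c = 0.5)
  expect_equal(gaussian_burst(seq(0, 10, 0.1), p0)$values, rep(0.5, 101))
  # peak value A / (sigma sqrt(2 pi)) + c for the aversive-average set
  pa <- canon$burst$aversive
  g <- gaussian_burst(pa$mu + seq(-30, 30) * 0.1, pa)
  peak <- pa$A / (pa$sigma * sqrt(2 * pi)) + pa$c
  expect_equal(max(g$values), peak, tolerance = 1e-9)
  expect_equal(peak, 1.178, tolerance = 1e-3)
  # symmetry about mu
  tt <- c(pa$mu - pa$sigma, pa$mu + pa$sigma)
  vv <- pa$A / (sqrt(2 * pi) * pa$sigma) *
    exp(-(tt - pa$mu)^2 / (2 * pa$sigma^2)) + pa$c
  expect_equal(vv[1], vv[2])
  expect_error(burst_params(1, 1, -0.1), "sigma")
})

test_that("all canonical coefficient sets satisfy Routh-Hurwitz stability", {
  for (th in canon$theta) {
    expect_true(scrf_stable(th))
    expect_gt(th$theta1 * th$theta2, th$theta3)
  }
  expect_false(scrf_stable(scrf_params(1, 0.1, 2, 0)))
})

test_that("the ODE solution honours analytic limits", {
  # zero input -> zero output
  z <- scrf_simulate(canon$theta$low_rate, scr_ts(rep(0, 100), 10))
  expect_equal(z$values, rep(0, 100))
  # steady state x_ss = -g u0 / theta3 for every canonical set
  u <- scr_ts(rep(1, 4000), rate = 10)
  for (th in canon$theta) {
    x <- scrf_simulate(th, u, gain = 1)
    expect_equal(x$values[4000], -1 / th$theta3,
                 tolerance = 1e-4)
  }
  # the low-rate value printed to 3 decimals
  xlow <- scrf_simulate(canon$theta$low_rate, u)
  expect_equal(xlow$values[4000], -6.592, tolerance = 1e-3)
  # linearity: response to a*u is a times the response
  tr <- build_input_train(c(2, 9), rate = 10, duration = 40)
  x1 <- scrf_simulate(canon$theta$aversive, tr)
  x3 <- scrf_simulate(canon$theta$aversive,
                      scr_ts(3 * tr$values, rate = 10))
  expect_lt(rel_l2_err(x3$values, 3 * x1$values), 1e-8)
  # superposition of two inputs
  u1 <- build_input_train(3, 10, 40)
  u2 <- build_input_train(15, 10, 40)
  both <- scrf_simulate(canon$theta$aversive,
                        scr_ts(u1$values + u2$values, 10))
  sep <- scrf_simulate(canon$theta$aversive, u1)$values +
    scrf_simulate(canon$theta$aversive, u2)$values
  expect_lt(rel_l2_err(both$values, sep), 1e-8)
  expect_warning(scrf_simulate(scrf_params(1, 0.1, 2, 0),
                               scr_ts(rep(0, 10), 10)), "stability")
})

test_that("impulse responses integrate to -1/theta3 and are solver-converged", {
  for (th in canon$theta) {
    ir <- scrf_impulse_response(th, dt = 0.1, duration = 400)
    expect_equal(sum(ir$values) * 0.1, -1 / th$theta3, tolerance = 1e-3)
  }
  th <- canon$theta$low_rate
  # gaussian-input response equals delta response convolved with the kernel
  ir_d <- scrf_impulse_response(th, duration = 60)
  ir_g <- scrf_impulse_response(th, duration = 30, input_kind = "gaussian")
  u <- scr_ts(dnorm(seq(0, 60, 0.1), 1.5, 0.3), rate = 10)
  conv <- convolve_predict(ir_d, u)
  expect_lt(rel_l2_err(conv$values[16:301], ir_g$values[1:286]), 1e-3)
  # halving dt barely changes the response
  f1 <- scrf_impulse_response(th, dt = 0.1, duration = 30)
  f2 <- scrf_impulse_response(th, dt = 0.05, duration = 30)
  expect_lt(rel_l2_err(f2$values[seq(1, 601, 2)], f1$values), 1e-4)
})

test_that("the RK4 solution matches an independent stiff ODE solver", {
  skip_if_not_installed("deSolve")
  th <- canon$theta$aversive
  u <- build_input_train(c(2, 7, 19), rate = 10, duration = 40, sigma_in = 0.3)
  mine <- scrf_simulate(th, u, gain = 1.4)
  uf <- approxfun(ts_time(u), u$values, rule = 2)
  deriv <- function(t, y, parms) {
    list(c(y[2], y[3],
           -th$theta1 * y[3] - th$theta2 * y[2] - th$theta3 * y[1] -
             1.4 * uf(t - th$theta4)))
  }
  sol <- deSolve::lsoda(c(0, 0, 0), ts_time(u), deriv, NULL,
                        rtol = 1e-10, atol = 1e-12)
  expect_lt(rel_l2_err(mine$values, sol[, 2]), 1e-4)
})

test_that("convolution prediction is a faithful LTI pathway", {
  th <- canon$theta$oddball
  th0 <- scrf_params(th$theta1, th$theta2, th$theta3, 0)
  ir <- scrf_impulse_response(th0, duration = 60)
  # unit impulse at sample k shifts the kernel
  n <- 300
  imp <- scr_ts(c(rep(0, 50), 1, rep(0, n - 51)), rate = 10)
  out <- convolve_predict(ir, imp, gain = 2)
  expect_equal(out$values[51:n], 2 * 0.1 * ir$values[1:(n - 50)],
               tolerance = 1e-12)
  expect_equal(convolve_predict(ir, imp, gain = 0)$values, rep(0, n))
  # agreement with the ODE pathway on a burst train (delay included)
  tr <- build_input_train(c(2, 9, 17.5), rate = 10, duration = 60)
  x_ode <- scrf_simulate(th, tr, gain = 1.3)
  x_conv <- scrf_predict(th, tr, gain = 1.3)
  expect_lt(rel_l2_err(x_conv$values, x_ode$values), 1e-3)
  expect_error(convolve_predict(ir, scr_ts(1:10, rate = 20)), "rate")
})

test_that("convolution and ODE pathways agree on random stable systems", {
  set.seed(42)
  for (i in 1:10) {
    th <- random_stable_theta()
    onsets <- sort(runif(4, 3, 40))
    tr <- build_input_train(onsets, rate = 10, duration = 60,
                            amplitudes = runif(4, 0.5, 2))
    a <- scrf_simulate(th, tr)$values
    b <- scrf_predict(th, tr)$values
    expect_lt(rel_l2_err(b, a), 1e-3)
  }
})

test_that("input trains are unit-area Gaussians at the onsets", {
  tr <- build_input_train(10, rate = 10, duration = 30, sigma_in = 0.3)
  expect_equal(sum(tr$values) * 0.1, 1, tolerance = 1e-3)
  tr2 <- build_input_train(c(5, 25), rate = 10, duration = 40)
  expect_equal(sum(tr2$values) * 0.1, 2, tolerance = 1e-3)
  mid <- tr2$values[round(15 * 10)]
  expect_lt(mid, 1e-8)                        # bumps do not overlap
  expect_equal(build_input_train(numeric(0), 10, 5)$values, rep(0, 50))
  expect_error(build_input_train(10, 10, 5), "within")
})

test_that("time invariance: shifting the input shifts the response", {
  th <- canon$theta$low_rate
  u1 <- build_input_train(5, rate = 10, duration = 60)
  u2 <- build_input_train(12, rate = 10, duration = 60)
  x1 <- scrf_simulate(th, u1)$values
  x2 <- scrf_simulate(th, u2)$values
  k <- 70  # 7 s at 10 Hz
  expect_lt(rel_l2_err(x2[(k + 1):600], x1[1:(600 - k)]), 1e-3)
})
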