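test_that("amplitude measurement recovers isolated and train responses", {
  kp <- kernel_params()
  kern <- make_kernel(kp, 50000)$samples
  x <- numeric(25000)
  i0 <- 5001
  x[i0:(i0 + length(kern) - 1)] <- 100 * kern
  tr <- ephys_trace(x, 50000, kind = "current")
  amp <- measure_train_amplitudes(tr, stim_protocol(0.1))
  expect_equal(amp, 100, tolerance = 1e-9)

  expect_error(measure_train_amplitudes(tr, stim_protocol()), "no stimuli")
  expect_error(measure_train_amplitudes(tr, stim_protocol(0.499)), "bounds")

  # noiseless 100 Hz train with overlap: within 5% of ground truth
  proto <- train_protocol(40, 100)
  dp <- depletion_params(n0 = 100, p_r = 0.2, q = 1,
                         repl_rate = 0.04 * 100 * 100)
  g <- gen_evoked_sweeps(dp, proto, kp, noise_sd = 0)
  amps <- measure_train_amplitudes(g$sweeps$sweeps[[1]], proto)
  expect_lt(max(abs(amps - g$truth$amplitudes[1, ]) /
                  g$truth$amplitudes[1, ]), 0.05)
})

test_that("normalisation and paired-pulse ratio follow their definitions", {
  expect_equal(normalize_amplitudes(c(200, 100, 50)), c(1, 0.5, 0.25))
  expect_equal(normalize_amplitudes(3 * c(200, 100, 50)),
               normalize_amplitudes(c(200, 100, 50)))  # scale invariance
  expect_error(normalize_amplitudes(c(0, 1)), "first amplitude")

  expect_equal(paired_pulse_ratio(c(100, 97)), 0.97)
  expect_equal(paired_pulse_ratio(c(5, 5)), 1)
  expect_error(paired_pulse_ratio(100), ">= 2")

  # model prediction at p = 0.2 with 0.04 per-interval replenishment
  dp <- depletion_params(n0 = 100, p_r = 0.2, q = 1,
                         repl_rate = 0.04 * 100 / 0.05)
  norm <- simulate_train(dp, paired_pulse_protocol(0.05))$norm_amplitude
  expect_equal(paired_pulse_ratio(norm), 1 - 0.2 + 0.04, tolerance = 1e-12)
})

test_that("steady-state depression averages the last responses", {
  expect_equal(steady_state_depression(rep(1, 40)), 1)
  expect_lt(steady_state_depression(0.5^(0:39)), 1e-9)
  expect_error(steady_state_depression(c(1, 0.5), n_last = 5), "n_last")
  dp <- depletion_params(n0 = 100, p_r = 0.2, q = 1,
                         repl_rate = 0.04 * 100 * 100)
  norm <- simulate_train(dp, train_protocol(40, 100))$norm_amplitude
  expect_lt(abs(steady_state_depression(norm) - 0.2), 1e-3)
})

test_that("train method recovers model parameters from the cumulative plot", {
  cf <- closed_form_train(depletion_params(n0 = 100, p_r = 0.2, q = 1,
                                           repl_rate = 0.04 * 100 * 100), 40)
  est <- train_method(cf)
  expect_equal(est$fit_slope, 0.200, tolerance = 0.001 / 0.2)
  expect_equal(est$rrp_rel, 4.00, tolerance = 0.02 / 4)
  expect_equal(est$p_r_est, 0.250, tolerance = 0.002 / 0.25)
  expect_true(est$valid)

  # r = 0, p = 0.5: residual (1-p)^33 is negligible, estimate exact
  geo <- closed_form_train(depletion_params(p_r = 0.5), 40)
  expect_equal(train_method(geo)$p_r_est, 0.5, tolerance = 1e-6)

  # non-depressing input flags invalid instead of crashing
  flat <- train_method(rep(1, 40))
  expect_false(flat$valid)
  expect_true(is.na(flat$p_r_est))

  expect_error(train_method(rep(1, 10)), "shorter")
})

test_that("EQ method is exact for geometric depression", {
  # p = 0.2: response vs prior cumulative is exactly linear, x-intercept 5
  geo <- (1 - 0.2)^(0:39)
  est <- eq_method(geo)
  expect_equal(est$rrp_rel, 5, tolerance = 1e-12)
  expect_equal(est$p_r_est, 0.2, tolerance = 1e-12)

  # closed form 1/p for any p
  est15 <- eq_method((1 - 0.15)^(0:39))
  expect_equal(est15$rrp_rel, 1 / 0.15, tolerance = 1e-12)

  ones <- eq_method(rep(1, 40))
  expect_false(ones$valid)
  expect_error(eq_method(c(1, 0.5)), "n_points")
})

test_that("estimators are scale-invariant and match textbook OLS", {
  set.seed(13)
  for (i in 1:20) {
    norm <- normalize_amplitudes(abs(rnorm(40, 100, 30)) + 1)
    # scale invariance through normalisation
    expect_equal(train_method(normalize_amplitudes(7.3 * norm))$fit_slope,
                 train_method(norm)$fit_slope)
    # train method vs explicit OLS on the cumulative curve
    cum <- cumsum(norm)
    o <- ols_oracle(33:40, cum[33:40])
    est <- train_method(norm)
    # QR-based and raw-sum OLS agree to rounding (the uncentered design
    # at k ~ 40 leaves ~1e-11 relative numerical noise)
    expect_equal(est$fit_intercept, unname(o["intercept"]), tolerance = 1e-9)
    expect_equal(est$fit_slope, unname(o["slope"]), tolerance = 1e-9)
    # EQ method vs explicit OLS on response-vs-prior-cumulative
    x <- c(0, cum[1:4]); y <- norm[1:5]
    oe <- ols_oracle(x, y)
    eq <- eq_method(norm)
    if (eq$valid)
      expect_equal(eq$rrp_rel, unname(-oe["intercept"] / oe["slope"]),
                   tolerance = 1e-9)
  }
})

test_that("EQ is exact and train converges for zero-replenishment inputs", {
  for (p in seq(0.05, 0.9, by = 0.05)) {
    geo <- (1 - p)^(0:39)
    expect_equal(eq_method(geo)$p_r_est, p, tolerance = 1e-10)
    # the train estimate equals analytic OLS on the same cumulative, and
    # its deterministic bias decays with the residual pool (1-p)^33:
    # about 3 * (1-p)^33, i.e. under 0.1% once p reaches 0.25
    o <- ols_oracle(33:40, cumsum(geo)[33:40])
    expect_equal(train_method(geo)$p_r_est, 1 / unname(o["intercept"]),
                 tolerance = 1e-9)
    if (p >= 0.25)
      expect_rel_error(train_method(geo)$p_r_est, p, 1e-3)
  }
})
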