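test_that("kernel is peak-normalized with the requested kinetics", {
  kp <- kernel_params(tau_rise = 0.5, tau_fast = 4, tau_slow = 12,
                      fast_fraction = 0.6)
  k <- make_kernel(kp, 50000)
  expect_equal(max(abs(k$samples)), 1)
  expect_true(all(k$samples <= 0))  # inward by default
  expect_lt(abs(k$samples[length(k$samples)]), 0.05)

  # near-instant rise, single decay component: post-peak tail is e^(-t/tau)
  kp2 <- kernel_params(tau_rise = 1e-4, tau_fast = 5, tau_slow = 5,
                       fast_fraction = 1)
  k2 <- make_kernel(kp2, 50000, duration_ms = 40)
  i_pk <- which.max(abs(k2$samples))
  t_ms <- (seq_along(k2$samples) - i_pk) / 50
  tail <- -k2$samples[t_ms >= 1 & t_ms <= 20]
  expected <- exp(-t_ms[t_ms >= 1 & t_ms <= 20] / 5) /
    max(abs(k2$samples)) * abs(k2$samples[i_pk])
  expect_lt(max(abs(tail - expected) / expected), 1e-4)
  # and the 10-90 rise collapses to under two sample periods
  r <- event_kinetics(ephys_trace(c(rep(0, 100), k2$samples), 50000,
                                  kind = "current"))
  expect_lt(r$rise_10_90, 2 * 0.02)

  expect_error(kernel_params(tau_fast = 10, tau_slow = 5), "tau_slow")
  expect_error(make_kernel(kp, 50000, duration_ms = 10), "duration")
})

test_that("mini generator is reproducible and Poisson-counted", {
  g1 <- gen_mini_trace(rate = 80, duration = 5, seed = 21)
  g2 <- gen_mini_trace(rate = 80, duration = 5, seed = 21)
  expect_identical(g1$trace$samples, g2$trace$samples)
  expect_identical(g1$truth$times, g2$truth$times)

  # event count within 3 sd of the Poisson expectation
  lambda <- 80 * 60
  g <- gen_mini_trace(rate = 80, duration = 60, noise_sd = 0, seed = 4)
  expect_lt(abs(length(g$truth$times) - lambda), 3 * sqrt(lambda))

  expect_error(gen_mini_trace(rate = -1, duration = 1), "rate")
  expect_error(gen_mini_trace(rate = 1, duration = 1, noise_sd = -2), "noise_sd")
})

test_that("noiseless mini trace is exactly the sum of scaled kernels", {
  kp <- kernel_params()
  g <- gen_mini_trace(rate = 1.2, duration = 3, noise_sd = 0, seed = 8,
                      kp = kp)
  kern <- make_kernel(kp, 50000)$samples
  manual <- numeric(length(g$trace$samples))
  for (e in seq_along(g$truth$times)) {
    i0 <- round(g$truth$times[e] * 50000) + 1
    idx <- i0:min(length(manual), i0 + length(kern) - 1)
    manual[idx] <- manual[idx] + g$truth$amplitudes[e] * kern[seq_along(idx)]
  }
  expect_equal(g$trace$samples, manual)
})

test_that("evoked sweeps carry exact ground truth through summation", {
  proto <- train_protocol(40, 100)
  dp <- depletion_params(n0 = 100, p_r = 0.2, q = 1,
                         repl_rate = 0.04 * 100 * 100)

  # single stimulus: rendered peak equals pr * n0 * q
  one <- gen_evoked_sweeps(dp, stim_protocol(0.02), noise_sd = 0)
  expect_equal(min(one$sweeps$sweeps[[1]]$samples), -0.2 * 100 * 1,
               tolerance = 1e-10)

  # amplitude measurement recovers ground truth within 5% even when the
  # decay is five times the inter-stimulus interval (summation stress)
  kp_slow <- kernel_params(tau_rise = 0.7, tau_fast = 6.25, tau_slow = 50,
                           fast_fraction = 0.7)
  g <- gen_evoked_sweeps(dp, proto, kp_slow, noise_sd = 0)
  amps <- measure_train_amplitudes(g$sweeps$sweeps[[1]], proto)
  expect_lt(max(abs(amps - g$truth$amplitudes[1, ]) /
                  g$truth$amplitudes[1, ]), 0.05)

  # stochastic sweep means approach the deterministic trajectory
  dps <- depletion_params(n0 = 1000, p_r = 0.2, q = 1,
                          repl_rate = 0.04 * 1000 * 100, mode = "stochastic")
  gs <- gen_evoked_sweeps(dps, proto, n_sweeps = 10, seed = 5)
  det <- simulate_train(dp, proto)$norm_amplitude
  mean_amps <- colMeans(gs$truth$amplitudes)
  expect_lt(max(abs(mean_amps / mean_amps[1] - det)), 0.05)
})

test_that("AP templates reproduce requested features by construction", {
  f <- ap_feature_targets(threshold = -40, amplitude = 80, half_width = 0.4,
                          max_rise = 400, max_fall = 150, ahp = 12)
  g <- gen_ap_sweeps(f, spont_rate = 10, duration = 0.5)
  tr <- g$sweeps$sweeps[[1]]
  expect_equal(max(tr$samples), -40 + 80)   # peak = threshold + amplitude

  # infeasible half-width (below the triangular minimum) errors out
  expect_error(ap_feature_targets(amplitude = 80, half_width = 0.2,
                                  max_rise = 300, max_fall = 150),
               "infeasible")
})

test_that("regular spontaneous scheduler fires exactly rate * duration spikes", {
  g <- gen_ap_sweeps(spont_rate = 50, duration = 1)
  expect_equal(nrow(g$truth$spikes), 50L)
  expect_equal(nrow(detect_spikes(g$sweeps$sweeps[[1]])), 50L)
})

test_that("leaky-integrator latency matches the closed form within a sample", {
  vb <- -60; vth <- -42; i_pa <- 50; r_m <- 500
  v_inf <- vb + i_pa * r_m / 1000
  tau_m <- 0.0384 / log((v_inf - vb) / (v_inf - vth))   # latency 38.4 ms
  g <- gen_ap_sweeps(ap_feature_targets(),
                     step_protocol(amplitude = i_pa),
                     r_m = r_m, tau_m = tau_m)
  expect_equal(g$truth$latency_ms, 38.4, tolerance = 1e-9)
  met <- evoked_firing_metrics(g$sweeps$sweeps[[1]],
                               step_protocol(amplitude = i_pa))
  expect_lt(abs(met$latency_ms - 38.4), 0.02)  # one sample at 50 kHz
})
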