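test_that("parameter validation rejects out-of-range values", {
  expect_error(depletion_params(p_r = 1.2), "p_r")
  expect_error(depletion_params(p_r = -0.1), "p_r")
  expect_error(depletion_params(n0 = 0), "n0")
  expect_error(depletion_params(q = -1), "q")
  expect_error(depletion_params(repl_rate = -5), "repl_rate")
  dp <- depletion_params(mode = "stochastic")
  expect_error(simulate_train(dp, train_protocol(4, 100)), "seed")
  expect_error(simulate_recovery(depletion_params(), train_protocol(4, 100),
                                 numeric(0)), "non-empty")
})

test_that("deterministic train follows the depletion recursion exactly", {
  # no replenishment, p = 0.5: amplitudes halve geometrically
  dp <- depletion_params(n0 = 10, p_r = 0.5, q = 1)
  ser <- simulate_train(dp, train_protocol(4, 100))
  expect_equal(ser$amplitude, c(5, 2.5, 1.25, 0.625))
  expect_equal(ser$norm_amplitude[1], 1)

  # replenishment of 0.04 n0 per interval with p = 0.2 converges to r/p
  dp2 <- depletion_params(n0 = 100, p_r = 0.2, q = 1,
                          repl_rate = 0.04 * 100 * 100)
  ser2 <- simulate_train(dp2, train_protocol(90, 100))
  expect_equal(ser2$norm_amplitude[90], 0.2, tolerance = 1e-6)

  # explicit-loop oracle agrees everywhere
  expect_equal(ser2$norm_amplitude[1:40],
               depletion_oracle(100, 0.2, 0.04 * 100, 40))
})

test_that("closed form matches the simulator to near machine precision", {
  set.seed(31)
  for (i in 1:20) {
    p <- runif(1, 0.05, 0.9)
    r <- runif(1, 0, 0.8 * p)   # keep below the fixed point
    dp <- depletion_params(n0 = 50, p_r = p, q = 2, repl_rate = r * 50 * 100)
    sim <- simulate_train(dp, train_protocol(40, 100))$norm_amplitude
    cf <- closed_form_train(dp, 40, isi = 0.01)
    expect_lt(max(abs(sim - cf)), 1e-12)
  }
  expect_equal(closed_form_train(depletion_params(p_r = 0.3), 5)[1], 1)
  expect_error(closed_form_train(depletion_params(p_r = 0), 5), "p_r")
})

test_that("vesicle bookkeeping conserves pool across steps", {
  dp <- depletion_params(n0 = 80, p_r = 0.3, q = 1, repl_rate = 150)
  ser <- simulate_train(dp, train_protocol(30, 100))
  for (k in 1:29) {
    expect_equal(ser$pool_before[k + 1],
                 ser$pool_before[k] - ser$released[k] + ser$replenished[k])
  }
  expect_true(all(ser$released <= ser$pool_before))
  expect_true(all(ser$pool_before >= 0))
})

test_that("zero replenishment gives non-increasing geometric depression", {
  for (p in c(0.1, 0.35, 0.7)) {
    dp <- depletion_params(n0 = 100, p_r = p, q = 1)
    norm <- simulate_train(dp, train_protocol(25, 100))$norm_amplitude
    expect_true(all(diff(norm) <= 0))
    expect_equal(norm, (1 - p)^(0:24))
  }
})

test_that("steady state rises with replenishment and falls with release probability", {
  ss <- function(p, repl) {
    dp <- depletion_params(n0 = 100, p_r = p, q = 1, repl_rate = repl)
    steady_state_depression(
      simulate_train(dp, train_protocol(40, 100))$norm_amplitude)
  }
  expect_true(ss(0.2, 300) > ss(0.2, 150))
  expect_true(ss(0.35, 300) < ss(0.2, 300))
})

test_that("stochastic release averages to the deterministic trajectory", {
  p <- 0.2
  proto <- train_protocol(10, 100)
  det <- simulate_train(depletion_params(n0 = 50, p_r = p, q = 1), proto)

  # large pool: a single stochastic run is within 1% of deterministic
  big <- depletion_params(n0 = 1e6, p_r = p, q = 1, mode = "stochastic")
  norm_big <- simulate_train(big, proto, seed = 3)$norm_amplitude
  expect_lt(max(abs(norm_big - det$norm_amplitude) / det$norm_amplitude),
            0.01)

  # small pool: the mean over many runs matches within 3 standard errors
  dp <- depletion_params(n0 = 50, p_r = p, q = 1, mode = "stochastic")
  runs <- vapply(1:10000, function(s)
    simulate_train(dp, proto, seed = s)$amplitude, numeric(10))
  m <- rowMeans(runs)
  se <- apply(runs, 1, sd) / sqrt(ncol(runs))
  expect_true(all(abs(m - det$amplitude) <= 3 * se))

  # identical seeds reproduce identical draws
  expect_identical(simulate_train(dp, proto, seed = 99),
                   simulate_train(dp, proto, seed = 99))
})

test_that("recovery follows the capped linear-refill closed form", {
  p <- 0.25; n0 <- 100; repl <- 350
  dp <- depletion_params(n0 = n0, p_r = p, q = 1, repl_rate = repl)
  proto <- train_protocol(40, 100)
  intervals <- c(0.05, 0.2, 0.5, 1, 2, 4)
  rec <- simulate_recovery(dp, proto, intervals)

  ser <- simulate_train(dp, proto)
  n_end <- ser$pool_before[40] - ser$released[40]
  expected <- pmin(1, n_end / n0 + repl * intervals / n0)
  expect_equal(rec$recovery_ratio, expected, tolerance = 1e-12)
  # ratios never decrease with interval and saturate at 1
  expect_true(all(diff(rec$recovery_ratio) >= 0))
  expect_equal(rec$recovery_ratio[length(intervals)], 1)

  # with no replenishment the ratio equals the end-of-train pool everywhere
  dp0 <- depletion_params(n0 = n0, p_r = p, q = 1, repl_rate = 0)
  rec0 <- simulate_recovery(dp0, proto, intervals)
  ser0 <- simulate_train(dp0, proto)
  n_end0 <- ser0$pool_before[40] - ser0$released[40]
  expect_equal(rec0$recovery_ratio, rep(n_end0 / n0, length(intervals)))
})
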