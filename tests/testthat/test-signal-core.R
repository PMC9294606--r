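test_that("trace construction enforces its invariants", {
  expect_error(ephys_trace(numeric(0), 50000), "at least one sample")
  expect_error(ephys_trace(c(1, NA), 50000), "finite")
  expect_error(ephys_trace(1:10, -1), "sampling_rate")
  tr <- ephys_trace(1:10, 50000, kind = "voltage")
  expect_equal(trace_unit(tr), "mV")
  expect_equal(trace_duration(tr), 10 / 50000)
  expect_equal(trace_times(tr)[1], 0)
})

test_that("trace write/read round-trips losslessly in both dialects", {
  set.seed(42)
  for (dialect in c("tsv", "csv")) {
    for (rep in 1:3) {
      tr <- ephys_trace(rnorm(1000) * 10^runif(1, -3, 3), 50000,
                        start_time = runif(1), kind = "current",
                        metadata = list(cell = "c07", sweep = 3L))
      path <- withr::local_tempfile(fileext = paste0(".", dialect))
      write_trace(tr, path, dialect)
      back <- read_trace(path, dialect)
      expect_identical(back$samples, tr$samples)
      expect_identical(back$sampling_rate, tr$sampling_rate)
      expect_identical(back$kind, tr$kind)
      expect_equal(back$start_time, tr$start_time)
      expect_equal(back$metadata$cell, "c07")
    }
  }
})

test_that("trace files are self-describing and validated on read", {
  path <- withr::local_tempfile()
  tr <- ephys_trace(sin(1:500), 50000, kind = "voltage")
  write_trace(tr, path)
  lines <- readLines(path)
  expect_true(any(grepl("^# sampling_rate: 50000", lines)))
  expect_true(any(grepl("^# units: mV", lines)))
  expect_equal(read_trace(path)$sampling_rate, 50000)

  # header without sampling_rate is a format error
  writeLines(c("# kind: current", "1", "2"), path)
  expect_error(read_trace(path), "sampling_rate")
  # non-monotonic explicit time column is a format error
  writeLines(c("# sampling_rate: 1000", "# kind: current",
               "0\t1", "0.002\t2", "0.001\t3"), path)
  expect_error(read_trace(path), "time column")
})

test_that("sweep averaging is exact, symmetric and linear", {
  tr <- function(x) ephys_trace(x, 50000, kind = "current")
  x <- sin(seq(0, 4 * pi, length.out = 2000))
  # identical sweeps average to themselves
  avg <- average_sweeps(sweep_set(list(tr(x), tr(x))))
  expect_equal(avg$samples, x)
  expect_equal(avg$metadata$n_averaged, 2)
  # +x and -x cancel
  expect_equal(average_sweeps(sweep_set(list(tr(x), tr(-x))))$samples,
               rep(0, length(x)))
  # linearity: avg(a * sweeps) = a * avg(sweeps)
  set.seed(7)
  sweeps <- replicate(4, rnorm(100), simplify = FALSE)
  a1 <- average_sweeps(sweep_set(lapply(sweeps, tr)))$samples
  a3 <- average_sweeps(sweep_set(lapply(sweeps, function(s) tr(3 * s))))$samples
  expect_equal(a3, 3 * a1)
})

test_that("averaging n noisy sweeps shrinks noise like 1/sqrt(n)", {
  set.seed(11)
  kernel <- exp(-(0:999) / 200)
  sigma <- 2
  resid_sd <- replicate(20, {
    sweeps <- lapply(1:10, function(i)
      ephys_trace(kernel + rnorm(1000, 0, sigma), 50000, kind = "current"))
    avg <- average_sweeps(sweep_set(sweeps))
    sd(avg$samples - kernel)
  })
  # residual SD should be near sigma / sqrt(10)
  expect_rel_error(mean(resid_sd), sigma / sqrt(10), 0.05)
})

test_that("sweep sets reject mismatched members and round-trip via container", {
  t1 <- ephys_trace(1:100, 50000, kind = "current")
  t2 <- ephys_trace(1:100, 25000, kind = "current")
  t3 <- ephys_trace(1:50, 50000, kind = "current")
  expect_error(sweep_set(list(t1, t2)), "sampling_rate")
  expect_error(sweep_set(list(t1, t3)), "length")
  expect_error(sweep_set(list()), "at least one")

  ss <- sweep_set(list(t1, t1), train_protocol(4, 100))
  dir <- withr::local_tempdir()
  write_sweep_set(ss, dir)
  back <- read_sweep_set(dir)
  expect_equal(length(back), 2L)
  expect_equal(back$sweeps[[1]]$samples, t1$samples)
  expect_equal(back$protocol$n_stimuli, 4L)
  expect_equal(back$protocol$train_frequency, 100)
})

test_that("protocol validation enforces ascending times and spacing", {
  expect_error(stim_protocol(c(0.1, 0.1)), "ascending")
  expect_error(stim_protocol(c(0.2, 0.1)), "ascending")
  expect_error(stim_protocol(c(0, 0.011), train_frequency = 100),
               "inconsistent")
  p <- train_protocol(40, 100)
  expect_equal(p$n_stimuli, 40L)
  expect_equal(diff(p$stimulus_times), rep(0.01, 39))
  expect_equal(paired_pulse_protocol(0.05)$stimulus_times[2] -
                 paired_pulse_protocol(0.05)$stimulus_times[1], 0.05)
  expect_error(stim_protocol(recovery_interval = -1), "recovery_interval")
})
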