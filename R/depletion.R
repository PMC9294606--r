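#' Parameters of the vesicle depletion/replenishment model
#'
#' The release model used throughout the package: a single readily
#' releasable pool of `n0` vesicles, a release probability `p_r` per
#' stimulus, a quantal postsynaptic amplitude `q` (pA per vesicle), and a
#' replenishment rate that is constant throughout the stimulus train. The
#' postsynaptic response to each stimulus is `N * Pr * Q`, where N is the
#' instantaneous pool size.
#'
#' @param n0 initial number of releasable vesicles (> 0).
#' @param p_r release probability per stimulus, in \[0, 1\].
#' @param q quantal amplitude in pA per vesicle (> 0).
#' @param repl_rate replenishment rate in vesicles per second (>= 0);
#'   integrated over each inter-stimulus interval.
#' @param mode `"deterministic"` (expected-value recursion) or
#'   `"stochastic"` (binomial release).
#' @param pool_cap logical; if TRUE the pool may not exceed `n0`. Off by
#'   default during trains; recovery simulations cap by default so that
#'   recovery ratios saturate at 1.
#' @return an object of class `depletion_params`.
#' @export
#' @examples
#' dp <- depletion_params(n0 = 10, p_r = 0.5, q = 1)
#' simulate_train(dp, train_protocol(4, 100))
depletion_params <- function(n0 = 100, p_r = 0.2, q = 1, repl_rate = 0,
                             mode = c("deterministic", "stochastic"),
                             pool_cap = FALSE) {
  mode <- match.arg(mode)
  if (!is_scalar_num(n0) || n0 <= 0) abort_fmt("n0 must be > 0")
  if (!is_scalar_num(p_r) || p_r < 0 || p_r > 1)
    abort_fmt("p_r must lie in [0, 1]")
  if (!is_scalar_num(q) || q <= 0) abort_fmt("q must be > 0")
  if (!is_scalar_num(repl_rate) || repl_rate < 0)
    abort_fmt("repl_rate must be >= 0")
  structure(list(n0 = n0, p_r = p_r, q = q, repl_rate = repl_rate,
                 mode = mode, pool_cap = isTRUE(pool_cap)),
            class = "depletion_params")
}

#' @export
print.depletion_params <- function(x, ...) {
  cat(sprintf(
    "<depletion_params> n0=%g, Pr=%g, Q=%g pA, repl=%g ves/s, %s%s\n",
    x$n0, x$p_r, x$q, x$repl_rate, x$mode,
    if (x$pool_cap) ", capped" else ""))
  invisible(x)
}

# one simulated train; returns the amplitude-series data frame
run_depletion <- function(params, times, pool0 = params$n0) {
  k <- length(times)
  dt <- diff(times)
  pool_before <- released <- replenished <- numeric(k)
  n <- pool0
  stochastic <- params$mode == "stochastic"
  for (i in seq_len(k)) {
    pool_before[i] <- n
    rel <- if (stochastic) {
      stats::rbinom(1L, max(0L, round(n)), params$p_r)
    } else {
      params$p_r * n
    }
    rel <- min(rel, n)          # can never release more than the pool holds
    released[i] <- rel
    n <- n - rel
    if (i < k) {
      inc <- params$repl_rate * dt[i]
      replenished[i] <- inc
      n <- n + inc
      if (params$pool_cap) n <- min(n, params$n0)
    }
  }
  amp <- released * params$q
  df <- data.frame(
    stimulus = seq_len(k), time = times, pool_before = pool_before,
    released = released, replenished = replenished, amplitude = amp,
    norm_amplitude = if (amp[1] > 0) amp / amp[1] else rep(NA_real_, k))
  class(df) <- c("amplitude_series", "data.frame")
  attr(df, "pool_end") <- n   # pool after last release (no post-train refill)
  df
}

#' Simulate evoked responses during a stimulus train
#'
#' Runs the depletion model over the stimulus times of `protocol`.
#' Deterministic mode follows the expected-value recursion
#' `release_k = p_r * n_k`, `n_(k+1) = n_k - release_k + repl_rate * dt_k`
#' (capped at `n0` when `pool_cap` is set); stochastic mode draws
#' `release_k ~ Binomial(round(n_k), p_r)` while replenishment stays
#' deterministic. Amplitudes are `release_k * q` in pA.
#'
#' @param params a [depletion_params()].
#' @param protocol a [stim_protocol()] with at least one stimulus.
#' @param seed RNG seed; required in stochastic mode so runs are
#'   reproducible.
#' @return an `amplitude_series` data frame with columns `stimulus`,
#'   `time`, `pool_before`, `released`, `replenished`, `amplitude` (pA)
#'   and `norm_amplitude` (first response = 1).
#' @export
simulate_train <- function(params, protocol, seed = NULL) {
  stopifnot(inherits(params, "depletion_params"),
            inherits(protocol, "stim_protocol"))
  if (protocol$n_stimuli < 1L) abort_fmt("protocol has no stimuli")
  if (params$mode == "stochastic" && is.null(seed))
    abort_fmt("stochastic mode requires a seed")
  with_seed(seed, run_depletion(params, protocol$stimulus_times))
}

#' Simulate recovery from depression
#'
#' Depletes the pool with the train in `protocol`, lets replenishment
#' continue during each recovery interval, then delivers a single test
#' stimulus. The recovery ratio is the test amplitude over the first
#' train amplitude. The pool is capped at `n0` during the interval by
#' default (a refilled pool cannot exceed its resting size, so ratios
#' saturate at 1).
#'
#' @param params a [depletion_params()].
#' @param protocol train protocol (the depleting train).
#' @param intervals recovery intervals in seconds (all > 0); the standard
#'   grid spans 50 to 4000 ms.
#' @param seed RNG seed (stochastic mode).
#' @param pool_cap cap the pool at `n0` during recovery (default TRUE).
#' @return a data frame with columns `interval`, `test_amplitude` and
#'   `recovery_ratio`.
#' @export
simulate_recovery <- function(params, protocol, intervals = recovery_intervals(),
                              seed = NULL, pool_cap = TRUE) {
  stopifnot(inherits(params, "depletion_params"),
            inherits(protocol, "stim_protocol"))
  if (length(intervals) < 1L) abort_fmt("intervals must be non-empty")
  if (any(intervals <= 0)) abort_fmt("intervals must be > 0")
  if (params$mode == "stochastic" && is.null(seed))
    abort_fmt("stochastic mode requires a seed")
  with_seed(seed, {
    out <- vapply(intervals, function(tau) {
      tr <- run_depletion(params, protocol$stimulus_times)
      n_end <- attr(tr, "pool_end")
      n_test <- n_end + params$repl_rate * tau
      if (pool_cap) n_test <- min(n_test, params$n0)
      rel <- if (params$mode == "stochastic") {
        stats::rbinom(1L, max(0L, round(n_test)), params$p_r)
      } else params$p_r * n_test
      c(rel * params$q, rel * params$q / tr$amplitude[1])
    }, numeric(2))
    data.frame(interval = intervals, test_amplitude = out[1, ],
               recovery_ratio = out[2, ])
  })
}

#' Default recovery-interval grid (50 ms to 4 s)
#' @param log_spaced use a log-spaced grid instead of the standard one.
#' @param n number of points for the log-spaced grid.
#' @return intervals in seconds.
#' @export
recovery_intervals <- function(log_spaced = FALSE, n = 8) {
  if (log_spaced) exp(seq(log(0.05), log(4), length.out = n))
  else c(0.05, 0.1, 0.25, 0.5, 1, 1.5, 2, 4)
}

#' Closed-form normalized train amplitudes (analytic oracle)
#'
#' For the deterministic, uncapped model with a regular inter-stimulus
#' interval, the normalized amplitude of stimulus k has the closed form
#' `a_k = r/p + (1 - r/p) (1 - p)^(k-1)` with `r = repl_rate * isi / n0`,
#' i.e. depression relaxes geometrically to the fixed point `r/p`. Used
#' as an independent check of [simulate_train()].
#'
#' @param params a deterministic, uncapped [depletion_params()] with
#'   `p_r > 0`.
#' @param n_stimuli number of stimuli.
#' @param isi regular inter-stimulus interval in seconds.
#' @return numeric vector of normalized amplitudes (first element 1).
#' @export
closed_form_train <- function(params, n_stimuli, isi = 0.01) {
  stopifnot(inherits(params, "depletion_params"))
  if (params$p_r <= 0) abort_fmt("closed form undefined for p_r = 0")
  if (params$mode != "deterministic" || params$pool_cap)
    abort_fmt("closed form requires deterministic, uncapped parameters")
  r <- params$repl_rate * isi / params$n0
  p <- params$p_r
  k <- seq_len(n_stimuli)
  r / p + (1 - r / p) * (1 - p)^(k - 1)
}
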