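#' Generate synthetic evoked-IPSC sweeps with ground truth
#'
#' For each sweep, draws a per-stimulus amplitude series from the
#' depletion model, renders each response as a scaled copy of the
#' peak-normalized kernel at the stimulus time (overlapping responses sum
#' linearly, so high-frequency trains show realistic summation), and adds
#' Gaussian noise. The ground truth carries the per-stimulus amplitudes
#' of every sweep.
#'
#' @param dp a [depletion_params()].
#' @param protocol a [stim_protocol()] with stimulus times (and
#'   optionally a recovery test pulse).
#' @param kp a [kernel_params()].
#' @param noise_sd Gaussian noise SD in pA.
#' @param n_sweeps number of sweeps to render.
#' @param seed RNG seed (required when `dp$mode == "stochastic"` or
#'   `noise_sd > 0`).
#' @param sampling_rate Hz.
#' @param post s of trace kept after the final stimulus.
#' @return list with `sweeps` (a [sweep_set()]) and `truth` (list with
#'   `amplitudes`, an n_sweeps x n_stimuli matrix in pA, and `series`,
#'   the per-sweep amplitude-series data frames).
#' @export
gen_evoked_sweeps <- function(dp, protocol, kp = kernel_params(),
                              noise_sd = 0, n_sweeps = 1, seed = NULL,
                              sampling_rate = 50000, post = 0.1) {
  stopifnot(inherits(dp, "depletion_params"),
            inherits(protocol, "stim_protocol"),
            inherits(kp, "kernel_params"))
  if (protocol$n_stimuli < 1L) abort_fmt("protocol has no stimuli")
  if ((dp$mode == "stochastic" || noise_sd > 0) && is.null(seed))
    abort_fmt("randomized generation requires a seed")
  with_seed(seed, {
    times <- protocol$stimulus_times
    dur <- max(times) + post
    n <- round(dur * sampling_rate)
    kernel <- make_kernel(kp, sampling_rate)$samples  # already signed by polarity
    series <- vector("list", n_sweeps)
    sweeps <- vector("list", n_sweeps)
    for (s in seq_len(n_sweeps)) {
      ser <- run_depletion(dp, times)
      series[[s]] <- ser
      x <- numeric(n)
      i0 <- round(times * sampling_rate) + 1L
      m <- length(kernel)
      for (e in seq_along(times)) {
        idx <- i0[e]:min(n, i0[e] + m - 1L)
        x[idx] <- x[idx] + ser$amplitude[e] * kernel[seq_along(idx)]
      }
      if (noise_sd > 0)
        x <- x + band_limited_noise(n, noise_sd, sampling_rate)
      sweeps[[s]] <- ephys_trace(x, sampling_rate, 0, "current",
                                 metadata = list(generator = "gen_evoked_sweeps",
                                                 sweep = s))
    }
    amps <- do.call(rbind, lapply(series, `[[`, "amplitude"))
    list(sweeps = sweep_set(sweeps, protocol),
         truth = list(amplitudes = amps, series = series, seed = seed))
  })
}
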