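#' Postsynaptic-current kernel parameters
#'
#' Shape parameters of the unitary synaptic-current waveform used by the
#' synthetic generators and by the template detector: a single-exponential
#' rise and a biexponential decay. Defaults are the wild-type mIPSC
#' kinetics of cerebellar nuclear neurons (tau_fast 6.25 ms, tau_slow
#' 13.4 ms; tau_rise 0.7 ms gives a 10-90 rise time of about 1.54 ms).
#'
#' @param tau_rise rise time constant in ms (> 0).
#' @param tau_fast fast decay time constant in ms (> 0).
#' @param tau_slow slow decay time constant in ms (>= tau_fast).
#' @param fast_fraction weight of the fast decay component, in \[0, 1\].
#' @param polarity `"inward"` (negative deflection; IPSCs recorded with a
#'   high-chloride internal solution) or `"outward"`.
#' @return an object of class `kernel_params`.
#' @export
kernel_params <- function(tau_rise = 0.7, tau_fast = 6.25, tau_slow = 13.4,
                          fast_fraction = 0.7,
                          polarity = c("inward", "outward")) {
  polarity <- match.arg(polarity)
  if (!is_scalar_num(tau_rise) || tau_rise <= 0) abort_fmt("tau_rise must be > 0")
  if (!is_scalar_num(tau_fast) || tau_fast <= 0) abort_fmt("tau_fast must be > 0")
  if (!is_scalar_num(tau_slow) || tau_slow < tau_fast)
    abort_fmt("tau_slow must be >= tau_fast")
  if (!is_scalar_num(fast_fraction) || fast_fraction < 0 || fast_fraction > 1)
    abort_fmt("fast_fraction must lie in [0, 1]")
  structure(list(tau_rise = tau_rise, tau_fast = tau_fast,
                 tau_slow = tau_slow, fast_fraction = fast_fraction,
                 polarity = polarity),
            class = "kernel_params")
}

#' @export
print.kernel_params <- function(x, ...) {
  cat(sprintf(
    "<kernel_params> rise %g ms; decay %g/%g ms (w=%g); %s\n",
    x$tau_rise, x$tau_fast, x$tau_slow, x$fast_fraction, x$polarity))
  invisible(x)
}

#' Render a peak-normalized synaptic-current kernel
#'
#' `k(t) = (1 - exp(-t/tau_rise)) * (w exp(-t/tau_fast) +
#' (1-w) exp(-t/tau_slow))`, peak-normalized to magnitude 1 and signed by
#' polarity.
#'
#' @param kp a [kernel_params()].
#' @param sampling_rate Hz.
#' @param duration_ms kernel duration in ms; must cover at least
#'   5 * tau_slow (the default).
#' @return an `ephys_trace` (current) of unit peak magnitude.
#' @export
make_kernel <- function(kp, sampling_rate = 50000,
                        duration_ms = 5 * kp$tau_slow + 5 * kp$tau_rise) {
  stopifnot(inherits(kp, "kernel_params"))
  if (duration_ms < 5 * kp$tau_slow)
    abort_fmt("kernel duration must be at least 5 * tau_slow")
  t_ms <- seq(0, duration_ms, by = 1000 / sampling_rate)
  k <- (1 - exp(-t_ms / kp$tau_rise)) *
    (kp$fast_fraction * exp(-t_ms / kp$tau_fast) +
       (1 - kp$fast_fraction) * exp(-t_ms / kp$tau_slow))
  k <- k / max(abs(k))
  if (kp$polarity == "inward") k <- -k
  ephys_trace(k, sampling_rate, 0, "current",
              metadata = list(tau_rise = kp$tau_rise, tau_fast = kp$tau_fast,
                              tau_slow = kp$tau_slow,
                              fast_fraction = kp$fast_fraction,
                              polarity = kp$polarity))
}

# NOTE: kernel addition into long traces is done in place at the call
# sites (x[idx] <- x[idx] + amp * kernel[...]) rather than through a
# helper: passing a multi-megasample vector into a function forces R to
# copy it on modification, which dominates runtime when thousands of
# events are rendered or subtracted.
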