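#' Measure evoked response amplitudes in a train
#'
#' For each stimulus, the amplitude is the extremum of the trace within a
#' post-stimulus window (0.5-8 ms by default) minus a local baseline
#' estimated from the 1 ms immediately preceding the stimulus, returned
#' as a positive magnitude. The baseline is a straight line fitted to
#' the pre-stimulus segment and extrapolated under the response: during
#' high-frequency trains each response rides on the decaying tail of its
#' predecessors, and a flat baseline would systematically underestimate
#' late amplitudes, while the local linear extrapolation tracks the tail
#' to within a few percent even when the decay is much slower than the
#' inter-stimulus interval.
#'
#' @param trace an [ephys_trace()] (current).
#' @param protocol a [stim_protocol()] whose stimulus windows lie inside
#'   the trace.
#' @param window post-stimulus search window in seconds, `c(from, to)`.
#' @param baseline_s pre-stimulus baseline duration in seconds.
#' @return numeric vector of amplitudes (pA magnitudes), one per
#'   stimulus (including the recovery test pulse if the protocol has one
#'   as an explicit stimulus time).
#' @export
measure_train_amplitudes <- function(trace, protocol,
                                     window = c(0.0005, 0.008),
                                     baseline_s = 0.001) {
  stopifnot(inherits(trace, "ephys_trace"), inherits(protocol, "stim_protocol"))
  if (protocol$n_stimuli < 1L) abort_fmt("protocol has no stimuli")
  rate <- trace$sampling_rate
  n <- length(trace$samples)
  vapply(protocol$stimulus_times, function(ts) {
    i_stim <- round((ts - trace$start_time) * rate) + 1
    i_from <- i_stim + round(window[1] * rate)
    i_to <- i_stim + round(window[2] * rate)
    if (i_to > n || i_from < 1)
      abort_fmt("stimulus window at t=%g s exceeds trace bounds", ts)
    ib_from <- max(1, i_stim - round(baseline_s * rate))
    ib_to <- max(1, i_stim - 1)
    ib <- ib_from:ib_to
    if (length(ib) >= 2) {
      cf <- stats::lm.fit(cbind(1, ib), trace$samples[ib])$coefficients
      base <- cf[1] + cf[2] * (i_from:i_to)
    } else {
      base <- trace$samples[ib]
    }
    dev <- trace$samples[i_from:i_to] - base
    abs(dev[which.max(abs(dev))])
  }, numeric(1))
}

#' Normalize amplitudes to the first response
#'
#' Division by the first amplitude, the standard normalisation that
#' removes differences in the number of axons/synapses recruited by
#' extracellular stimulation.
#'
#' @param amps amplitude vector; `amps[1]` must be > 0.
#' @return normalized vector with first element 1.
#' @export
normalize_amplitudes <- function(amps) {
  if (length(amps) < 1L) abort_fmt("empty amplitude sequence")
  if (!is.finite(amps[1]) || amps[1] <= 0)
    abort_fmt("first amplitude must be > 0 for normalisation")
  amps / amps[1]
}

#' Paired-pulse ratio
#' @param amps amplitude vector of length >= 2 (raw or normalized).
#' @return second amplitude / first amplitude.
#' @export
paired_pulse_ratio <- function(amps) {
  if (length(amps) < 2L) abort_fmt("paired-pulse ratio needs >= 2 amplitudes")
  amps[2] / amps[1]
}

#' Steady-state depression
#'
#' Mean of the last `n_last` normalized amplitudes (the last 5 of a 40
#' stimulus, 100 Hz train in the standard protocol).
#'
#' @param norm normalized amplitude vector.
#' @param n_last number of trailing responses to average.
#' @return mean steady-state normalized amplitude.
#' @export
steady_state_depression <- function(norm, n_last = 5) {
  k <- length(norm)
  if (k < n_last) abort_fmt("need at least n_last = %d amplitudes", n_last)
  mean(norm[(k - n_last + 1):k])
}

new_train_estimates <- function(method, fit, fit_range, rrp_rel, p_r_est,
                                repl_slope_rel = NA_real_, valid = TRUE,
                                reason = NA_character_) {
  structure(list(method = method, rrp_rel = rrp_rel, p_r_est = p_r_est,
                 repl_slope_rel = repl_slope_rel,
                 fit_intercept = fit[["intercept"]],
                 fit_slope = fit[["slope"]], fit_r2 = fit[["r2"]],
                 fit_range = fit_range, valid = valid, reason = reason),
            class = "train_estimates")
}

#' @export
print.train_estimates <- function(x, ...) {
  cat(sprintf("<train_estimates: %s method>\n", x$method))
  if (!x$valid) {
    cat(sprintf("  INVALID estimate: %s\n", x$reason))
  } else {
    cat(sprintf("  relative RRP: %.4g   Pr: %.4g\n", x$rrp_rel, x$p_r_est))
    if (!is.na(x$repl_slope_rel))
      cat(sprintf("  replenishment slope: %.4g per stimulus\n",
                  x$repl_slope_rel))
  }
  cat(sprintf("  fit: intercept %.4g, slope %.4g, R2 %.4g over stimuli %d-%d\n",
              x$fit_intercept, x$fit_slope, x$fit_r2,
              min(x$fit_range), max(x$fit_range)))
  invisible(x)
}

#' @export
as.data.frame.train_estimates <- function(x, ...) {
  data.frame(method = x$method, rrp_rel = x$rrp_rel, p_r_est = x$p_r_est,
             repl_slope_rel = x$repl_slope_rel,
             fit_intercept = x$fit_intercept, fit_slope = x$fit_slope,
             fit_r2 = x$fit_r2, valid = x$valid)
}

#' Train-method estimate of Pr, relative RRP and replenishment
#'
#' Plots cumulative normalized amplitude against stimulus number, fits an
#' ordinary least-squares line over the late, linear portion of the curve
#' (stimuli 33-40 of a 40-stimulus train by default), and back-extrapolates:
#' the y-intercept is the readily releasable pool relative to the first
#' response (so `Pr = 1/intercept`, the first amplitude being 1), and the
#' slope is proportional to the vesicle replenishment rate.
#'
#' @param norm normalized amplitude vector (first element 1).
#' @param fit_range stimulus indices used for the line fit.
#' @return a `train_estimates` object (`method = "train"`). A
#'   non-positive y-intercept (e.g. a non-depressing input) flags the
#'   estimate invalid rather than erroring.
#' @export
train_method <- function(norm, fit_range = 33:40) {
  if (length(norm) < max(fit_range))
    abort_fmt("amplitude sequence shorter than fit range")
  cum <- cumsum(norm)
  fit <- ols_line(fit_range, cum[fit_range])
  b0 <- fit[["intercept"]]
  if (!is.finite(b0) || b0 <= 1e-8)   # tolerate rounding of an exact zero
    return(new_train_estimates("train", fit, fit_range, NA_real_, NA_real_,
                               fit[["slope"]], valid = FALSE,
                               reason = "non-positive y-intercept (no depression)"))
  new_train_estimates("train", fit, fit_range, rrp_rel = b0,
                      p_r_est = 1 / b0, repl_slope_rel = fit[["slope"]])
}

#' Elmqvist-Quastel estimate of Pr and relative RRP
#'
#' Plots each of the first `n_points` normalized amplitudes against the
#' cumulative amplitude of the *preceding* responses and fits an OLS line;
#' the x-intercept is the relative readily releasable pool and
#' `Pr = first amplitude / x-intercept = 1/x-intercept`. For a
#' depressing geometric train with no replenishment the relation is
#' exactly linear, and the estimate is exact. (The x-intercept is
#' identical under the inclusive cumulative convention; the exclusive
#' convention is used here.)
#'
#' @param norm normalized amplitude vector (first element 1).
#' @param n_points number of early points fitted (default 5).
#' @return a `train_estimates` object (`method = "EQ"`). A non-negative
#'   fitted slope (no depression) flags the estimate invalid.
#' @export
eq_method <- function(norm, n_points = 5) {
  if (length(norm) < n_points + 1L)
    abort_fmt("need at least n_points + 1 amplitudes")
  idx <- seq_len(n_points)
  x <- c(0, cumsum(norm)[idx[-n_points]])  # cumulative of preceding responses
  y <- norm[idx]
  fit <- ols_line(x, y)
  if (!is.finite(fit[["slope"]]) || fit[["slope"]] >= 0)
    return(new_train_estimates("EQ", fit, idx, NA_real_, NA_real_,
                               valid = FALSE,
                               reason = "non-negative slope (no depression)"))
  x_int <- -fit[["intercept"]] / fit[["slope"]]
  new_train_estimates("EQ", fit, idx, rrp_rel = x_int,
                      p_r_est = norm[1] / x_int)
}

#' Full train analysis of a measured sweep or average
#'
#' Convenience wrapper: measures amplitudes, normalizes, and returns the
#' paired-pulse ratio, steady-state depression and both cumulative-plot
#' estimators.
#'
#' @param trace averaged evoked trace.
#' @param protocol train protocol.
#' @param fit_range,n_points passed to [train_method()] / [eq_method()].
#' @return list with `amplitudes`, `norm`, `ppr`, `steady_state`,
#'   `train`, `eq`.
#' @export
analyze_train <- function(trace, protocol, fit_range = 33:40, n_points = 5) {
  amps <- measure_train_amplitudes(trace, protocol)
  norm <- normalize_amplitudes(amps)
  list(amplitudes = amps, norm = norm,
       ppr = paired_pulse_ratio(norm),
       steady_state = steady_state_depression(norm),
       train = train_method(norm, fit_range),
       eq = eq_method(norm, n_points))
}
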