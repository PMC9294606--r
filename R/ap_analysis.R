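# Spike detection and action-potential waveform measurement.

# central-difference derivative in mV/ms for a voltage trace
dvdt_mv_ms <- function(trace) {
  v <- trace$samples
  n <- length(v)
  d <- numeric(n)
  dt_ms <- 1000 / trace$sampling_rate
  d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dt_ms)
  d[1] <- d[2]; d[n] <- d[n - 1]
  d
}

# sub-sample onset refinement: intersect the local pre-onset slope with
# the rising-phase slope; falls back to NA when either fit is unusable
refine_onset <- function(tt, v, ic) {
  n <- length(v)
  if (ic < 6L || ic + 4L > n) return(NA_real_)
  sA <- (v[ic - 2L] - v[ic - 5L]) / (tt[ic - 2L] - tt[ic - 5L])
  sB <- (v[ic + 4L] - v[ic + 2L]) / (tt[ic + 4L] - tt[ic + 2L])
  if (!is.finite(sA) || !is.finite(sB) || sB - sA <= abs(sA) + 1e-9)
    return(NA_real_)
  tc <- ((v[ic - 2L] - sA * tt[ic - 2L]) - (v[ic + 3L] - sB * tt[ic + 3L])) /
    (sB - sA)
  if (tc < tt[ic - 2L] || tc > tt[ic + 2L]) return(NA_real_)
  tc
}

#' Detect action potentials in a voltage trace
#'
#' A spike is an upward crossing of the dV/dt threshold (20 mV/ms by
#' default) followed within 2 ms by a voltage peak above `min_peak`.
#' Crossing times are refined to sub-sample precision (interpolation of
#' dV/dt, then intersection of the pre-onset and rising slopes), and a
#' refractory window suppresses duplicate detections.
#'
#' @param trace a voltage [ephys_trace()].
#' @param dvdt_threshold spike-onset criterion in mV/ms.
#' @param min_peak minimum peak voltage in mV.
#' @param refractory_ms minimum separation between spike onsets (ms).
#' @return data frame with `time` (s, interpolated threshold crossing =
#'   spike onset), `peak_time` (s) and `peak` (mV), one row per spike.
#' @export
detect_spikes <- function(trace, dvdt_threshold = 20, min_peak = -20,
                          refractory_ms = 1) {
  stopifnot(inherits(trace, "ephys_trace"))
  if (trace$kind != "voltage") abort_fmt("detect_spikes needs a voltage trace")
  v <- trace$samples
  n <- length(v)
  d <- dvdt_mv_ms(trace)
  tt <- trace_times(trace)
  up <- which(d[-n] < dvdt_threshold & d[-1] >= dvdt_threshold)
  win <- round(0.002 * trace$sampling_rate)
  min_gap <- refractory_ms / 1000
  onsets <- peaks_t <- peaks_v <- numeric(0)
  last <- -Inf
  for (i in up) {
    t_on <- interp_crossing(tt, d, i, dvdt_threshold)
    t_ref <- refine_onset(tt, v, i + 1L)
    if (!is.na(t_ref)) t_on <- t_ref
    if (t_on - last < min_gap) next
    j <- i:min(n, i + win)
    i_pk <- j[which.max(v[j])]
    if (v[i_pk] < min_peak) next
    # require a genuine local maximum inside the window, not a ramp edge
    if (i_pk == max(j) && i_pk < n && v[i_pk + 1L] > v[i_pk]) next
    onsets <- c(onsets, t_on)
    peaks_t <- c(peaks_t, tt[i_pk])
    peaks_v <- c(peaks_v, v[i_pk])
    last <- t_on
  }
  data.frame(time = onsets, peak_time = peaks_t, peak = peaks_v)
}

#' Action-potential waveform features
#'
#' Measures the standard waveform descriptors of one spike. The
#' threshold is the membrane potential at the last upward dV/dt crossing
#' of `dvdt_threshold` before the peak (sub-sample interpolated);
#' amplitude is peak minus threshold; half-width is the width at
#' threshold + amplitude/2 with linear interpolation; maximal rise and
#' fall rates are the dV/dt extrema between threshold and the AHP
#' trough; and the AHP is measured from threshold down to the voltage
#' minimum within `ahp_window_ms` after the peak. The AHP reference is
#' the threshold voltage (not the pre-spike baseline); `max_fall` is
#' reported as a positive magnitude.
#'
#' @param trace a voltage [ephys_trace()].
#' @param spike_time spike onset or peak time (s), e.g. from
#'   [detect_spikes()].
#' @param dvdt_threshold onset criterion in mV/ms.
#' @param ahp_window_ms post-peak window searched for the AHP trough.
#' @return an `ap_features` list: `threshold` (mV), `amplitude` (mV),
#'   `half_width` (ms), `max_rise` (mV/ms), `max_fall` (mV/ms,
#'   magnitude), `ahp` (mV), `peak_time` (s).
#' @export
ap_features <- function(trace, spike_time, dvdt_threshold = 20,
                        ahp_window_ms = 10) {
  stopifnot(inherits(trace, "ephys_trace"))
  if (trace$kind != "voltage") abort_fmt("ap_features needs a voltage trace")
  v <- trace$samples
  n <- length(v)
  tt <- trace_times(trace)
  rate <- trace$sampling_rate
  d <- dvdt_mv_ms(trace)
  i_s <- trace_index(trace, spike_time)
  j <- i_s:min(n, i_s + round(0.002 * rate))
  i_pk <- j[which.max(v[j])]
  if (i_pk + round(ahp_window_ms / 1000 * rate) > n || i_pk <= 2L)
    abort_fmt("spike truncated at trace edge")
  # threshold: last upward dvdt crossing before the peak
  pre <- seq_len(i_pk - 1L)
  cross <- which(d[pre] < dvdt_threshold & d[pre + 1L] >= dvdt_threshold)
  if (!length(cross)) abort_fmt("no dV/dt threshold crossing before peak")
  ic <- max(cross)
  t_thr <- interp_crossing(tt, d, ic, dvdt_threshold)
  v_thr <- stats::approx(tt[c(ic, ic + 1L)], v[c(ic, ic + 1L)], t_thr)$y
  amplitude <- v[i_pk] - v_thr
  # AHP trough within the post-peak window
  w_ahp <- (i_pk + 1L):(i_pk + round(ahp_window_ms / 1000 * rate))
  i_tr <- w_ahp[which.min(v[w_ahp])]
  ahp <- v_thr - v[i_tr]
  # dV/dt extrema between threshold and trough
  max_rise <- max(d[ic:i_pk])
  max_fall <- abs(min(d[i_pk:i_tr]))
  # half-width at threshold + amplitude/2
  lvl <- v_thr + amplitude / 2
  upc <- which(v[ic:(i_pk - 1L)] < lvl & v[(ic + 1L):i_pk] >= lvl)
  dnc <- which(v[i_pk:(i_tr - 1L)] >= lvl & v[(i_pk + 1L):i_tr] < lvl)
  if (!length(upc) || !length(dnc))
    abort_fmt("half-amplitude level not crossed on both flanks")
  t_up <- interp_crossing(tt, v, ic + max(upc) - 1L, lvl)
  t_dn <- interp_crossing(tt, v, i_pk + dnc[1L] - 1L, lvl)
  structure(list(threshold = v_thr, amplitude = amplitude,
                 half_width = (t_dn - t_up) * 1000,
                 max_rise = max_rise, max_fall = max_fall, ahp = ahp,
                 peak_time = tt[i_pk]),
            class = "ap_features")
}

#' @export
print.ap_features <- function(x, ...) {
  cat(sprintf(
    paste0("<ap_features> threshold %.3g mV; amplitude %.3g mV; ",
           "half-width %.3g ms\n  max rise %.4g mV/ms; max fall %.4g mV/ms;",
           " AHP %.3g mV\n"),
    x$threshold, x$amplitude, x$half_width, x$max_rise, x$max_fall, x$ahp))
  invisible(x)
}

#' Evoked firing metrics for a current-step sweep
#'
#' @param trace a voltage [ephys_trace()].
#' @param protocol a [step_protocol()] (must define the step).
#' @param ... passed to [detect_spikes()].
#' @return list with `firing_rate` (Hz, spikes within the step divided
#'   by step duration), `latency_ms` (first spike onset minus step onset;
#'   `NA` when no spike) and `n_spikes`.
#' @export
evoked_firing_metrics <- function(trace, protocol, ...) {
  stopifnot(inherits(protocol, "stim_protocol"))
  if (is.null(protocol$step_onset)) abort_fmt("protocol lacks a current step")
  sp <- detect_spikes(trace, ...)
  on <- protocol$step_onset
  inside <- sp$time >= on & sp$time <= on + protocol$step_duration
  n <- sum(inside)
  list(firing_rate = n / protocol$step_duration,
       latency_ms = if (n > 0) 1000 * (sp$time[inside][1] - on) else NA_real_,
       n_spikes = n)
}

#' Spontaneous firing rate
#'
#' @param x a voltage [ephys_trace()] (spikes detected with defaults) or
#'   a numeric vector of spike times.
#' @param duration recording duration in seconds; taken from the trace
#'   when `x` is a trace.
#' @param ... passed to [detect_spikes()] when `x` is a trace.
#' @return firing rate in Hz (count / duration).
#' @export
spontaneous_rate <- function(x, duration = NULL, ...) {
  if (inherits(x, "ephys_trace")) {
    if (is.null(duration)) duration <- trace_duration(x)
    n <- nrow(detect_spikes(x, ...))
  } else {
    if (is.null(duration)) abort_fmt("duration is required for a spike-time vector")
    n <- length(x)
  }
  if (!is_scalar_num(duration) || duration <= 0) abort_fmt("duration must be > 0")
  n / duration
}

#' Input resistance from hyperpolarising steps
#'
#' Least-squares slope of steady-state voltage deflection against
#' injected current, constrained through the origin (a zero step gives a
#' zero deflection), reported in megaohm.
#'
#' @param steps data frame with columns `delta_i` (pA) and `delta_v`
#'   (mV); at least one non-zero current step.
#' @return input resistance in megaohm.
#' @export
input_resistance <- function(steps) {
  if (!is.data.frame(steps) || !all(c("delta_i", "delta_v") %in% names(steps)))
    abort_fmt("steps must have delta_i and delta_v columns")
  if (all(steps$delta_i == 0)) abort_fmt("need at least one non-zero step")
  slope <- sum(steps$delta_v * steps$delta_i) / sum(steps$delta_i^2)
  slope * 1000   # mV/pA -> megaohm
}
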