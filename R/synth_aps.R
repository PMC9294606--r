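#' Target features for a synthetic action-potential template
#'
#' Defines the waveform features a synthetic spike must have by
#' construction. The template is piecewise linear: a subthreshold
#' approach, a constant-slope rising phase (`max_rise`), a short flat
#' apex whose duration is chosen so the width at half amplitude equals
#' `half_width` exactly, a constant-slope falling phase (`max_fall`)
#' down to the after-hyperpolarisation trough at `threshold - ahp`, and a
#' brief flat trough so the sampled minimum equals the construction
#' trough regardless of sample alignment. Half-amplitude crossings fall
#' inside linear segments, so sub-sample interpolation recovers the
#' construction values exactly.
#'
#' Defaults follow wild-type evoked spikes of cerebellar nuclear
#' neurons: half-width 0.31 ms, maximum repolarisation rate 189.7 mV/ms,
#' AHP 15.5 mV; threshold, amplitude and rise slope are typical values
#' for these fast-spiking cells.
#'
#' @param threshold spike threshold in mV.
#' @param amplitude peak minus threshold in mV (> 0).
#' @param half_width width at half amplitude in ms; must exceed the
#'   triangular minimum `(amplitude/2) * (1/max_rise + 1/max_fall)`.
#' @param max_rise maximal depolarisation rate in mV/ms (> 20, so the
#'   rising phase crosses the detection criterion).
#' @param max_fall maximal repolarisation rate in mV/ms (> 0, magnitude).
#' @param ahp after-hyperpolarisation depth below threshold in mV (>= 0).
#' @return an object of class `ap_features_target`.
#' @export
ap_feature_targets <- function(threshold = -42, amplitude = 62,
                               half_width = 0.31, max_rise = 450,
                               max_fall = 189.7, ahp = 15.5) {
  if (amplitude <= 0) abort_fmt("amplitude must be > 0")
  if (max_rise <= 20) abort_fmt("max_rise must exceed 20 mV/ms")
  if (max_fall <= 0) abort_fmt("max_fall must be > 0")
  if (ahp < 0) abort_fmt("ahp must be >= 0")
  hw_min <- (amplitude / 2) * (1 / max_rise + 1 / max_fall)
  if (half_width <= hw_min)
    abort_fmt(paste0("half_width %.4g ms is infeasible for these slopes ",
                     "(minimum %.4g ms)"), half_width, hw_min)
  structure(list(threshold = threshold, amplitude = amplitude,
                 half_width = half_width, max_rise = max_rise,
                 max_fall = max_fall, ahp = ahp),
            class = "ap_features_target")
}

# piecewise-linear spike shape relative to the threshold crossing at t = 0
# (times in ms); trough_flat_ms keeps the sampled AHP minimum exact
spike_knots <- function(f, trough_flat_ms) {
  v_pk <- f$threshold + f$amplitude
  v_tr <- f$threshold - f$ahp
  t_rise <- f$amplitude / f$max_rise
  t_top <- f$half_width - (f$amplitude / 2) * (1 / f$max_rise + 1 / f$max_fall)
  t_fall <- (f$amplitude + f$ahp) / f$max_fall
  t <- cumsum(c(0, t_rise, t_top, t_fall, trough_flat_ms))
  list(t_ms = t,
       v = c(f$threshold, v_pk, v_pk, v_tr, v_tr),
       peak_ms = t[2], core_ms = t[5])
}

#' Generate synthetic action-potential sweeps with exact ground truth
#'
#' Renders current-clamp voltage sweeps containing spikes built from a
#' feature-parameterized template (see [ap_feature_targets()]), either
#' evoked by a current step or fired spontaneously.
#'
#' In step mode, spike times come from a leaky-integrator scheduler with
#' membrane resistance `r_m` and time constant `tau_m`: the first
#' threshold crossing after step onset occurs at the closed-form latency
#' `t = -tau_m * log(1 - (Vth - Vb) / (I * r_m))`, and after each
#' spike the integrator restarts from the AHP trough. The rendered
#' subthreshold path between crossings is linearised (it is analysed
#' only for spike detection, never for feature values), so every
#' rendered crossing time equals its scheduled time exactly.
#'
#' In spontaneous mode a regular scheduler fires `round(spont_rate *
#' duration)` spikes at evenly spaced threshold-crossing times.
#'
#' @param features an [ap_feature_targets()].
#' @param protocol a [step_protocol()] for evoked sweeps, or NULL.
#' @param spont_rate spontaneous firing rate in Hz (used when `protocol`
#'   is NULL).
#' @param duration sweep duration in seconds (spontaneous mode).
#' @param r_m membrane resistance in megaohm.
#' @param tau_m membrane time constant in seconds.
#' @param n_sweeps number of (identical, deterministic) sweeps.
#' @param sampling_rate Hz.
#' @param seed unused placeholder for interface symmetry with the other
#'   generators (the AP generator is fully deterministic).
#' @return list with `sweeps` (a [sweep_set()]) and `truth`: per-spike
#'   `onset_time` / `peak_time` (s), the construction `features`, and in
#'   step mode the closed-form first-spike `latency_ms`.
#' @export
#' @examples
#' g <- gen_ap_sweeps(spont_rate = 50, duration = 1)
#' nrow(g$truth$spikes)  # exactly 50
gen_ap_sweeps <- function(features = ap_feature_targets(), protocol = NULL,
                          spont_rate = NULL, duration = 1, r_m = 400,
                          tau_m = 0.02, n_sweeps = 1, sampling_rate = 50000,
                          seed = NULL) {
  stopifnot(inherits(features, "ap_features_target"))
  dt_ms <- 1000 / sampling_rate
  sk <- spike_knots(features, trough_flat_ms = 3 * dt_ms)
  v_tr <- features$threshold - features$ahp

  if (!is.null(protocol)) {
    if (is.null(protocol$step_onset)) abort_fmt("protocol lacks a current step")
    vb <- if (is.null(protocol$baseline_potential)) -60
          else protocol$baseline_potential
    if (vb >= features$threshold)
      abort_fmt("baseline potential must lie below threshold")
    i_pa <- protocol$step_amplitude
    v_inf <- vb + i_pa * r_m / 1000     # pA * Mohm = uV -> /1000 mV
    onset <- protocol$step_onset
    step_end <- onset + protocol$step_duration
    dur <- step_end + 0.05
    core_s <- sk$core_ms / 1000
    # schedule threshold crossings with the leaky integrator (closed form)
    crossings <- numeric(0)
    if (v_inf > features$threshold) {
      t_cross <- onset + tau_m * log((v_inf - vb) / (v_inf - features$threshold))
      v_from <- vb
      t_from <- onset
      while (t_cross + core_s <= step_end) {
        crossings <- c(crossings, t_cross)
        t_from <- t_cross + core_s
        v_from <- v_tr
        t_cross <- t_from +
          tau_m * log((v_inf - v_from) / (v_inf - features$threshold))
      }
    }
    kt <- c(0, onset); kv <- c(vb, vb)
    for (tc in crossings) {
      kt <- c(kt, tc + sk$t_ms / 1000)
      kv <- c(kv, sk$v)
    }
    # subthreshold tail: head toward the next (unreached) crossing, cut at
    # step end, then settle back to baseline
    if (length(crossings)) {
      t_last_end <- crossings[length(crossings)] + core_s
      t_next <- t_last_end +
        tau_m * log((v_inf - v_tr) / (v_inf - features$threshold))
      frac <- min(1, (step_end - t_last_end) / (t_next - t_last_end))
      v_at_end <- v_tr + frac * (features$threshold - v_tr)
    } else {
      v_at_end <- min(v_inf, features$threshold - 1)
    }
    kt <- c(kt, step_end, step_end + 0.02, dur)
    kv <- c(kv, v_at_end, vb, vb)
    latency_ms <- if (length(crossings)) 1000 * (crossings[1] - onset)
                  else NA_real_
    spikes <- data.frame(onset_time = crossings,
                         peak_time = crossings + sk$peak_ms / 1000)
  } else {
    if (is.null(spont_rate) || spont_rate <= 0)
      abort_fmt("either a step protocol or a positive spont_rate is required")
    vb <- v_tr + 5   # inter-spike baseline sits above the AHP trough
    n_spk <- round(spont_rate * duration)
    crossings <- (seq_len(n_spk) - 0.5) / spont_rate
    approach_s <- 0.002
    recover_s <- (vb - v_tr) / 2 / 1000   # 2 mV/ms climb out of the AHP
    if (n_spk > 1 && diff(crossings)[1] < approach_s + sk$core_ms / 1000 + recover_s)
      abort_fmt("spont_rate too high for the template duration")
    dur <- duration
    kt <- 0; kv <- vb
    for (tc in crossings) {
      kt <- c(kt, tc - approach_s, tc + sk$t_ms / 1000)
      kv <- c(kv, vb, sk$v)
      t_end <- tc + sk$core_ms / 1000
      kt <- c(kt, t_end + recover_s)
      kv <- c(kv, vb)
    }
    kt <- c(kt, dur); kv <- c(kv, vb)
    latency_ms <- NA_real_
    spikes <- data.frame(onset_time = crossings,
                         peak_time = crossings + sk$peak_ms / 1000)
  }

  keep <- !duplicated(kt)
  kt <- kt[keep]; kv <- kv[keep]
  if (any(diff(kt) <= 0)) abort_fmt("internal error: template knots overlap")
  tt <- seq(0, dur - 1 / sampling_rate, by = 1 / sampling_rate)
  v <- stats::approx(kt, kv, xout = tt, rule = 2)$y
  sweep <- ephys_trace(v, sampling_rate, 0, "voltage",
                       metadata = list(generator = "gen_ap_sweeps"))
  sweeps <- sweep_set(rep(list(sweep), n_sweeps), protocol)
  list(sweeps = sweeps,
       truth = list(spikes = spikes, features = features,
                    latency_ms = latency_ms, r_m = r_m, tau_m = tau_m))
}
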