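#' Stimulation / current-step protocol
#'
#' Describes the timing of a recording protocol: extracellular stimulus
#' times for evoked synaptic responses, an optional recovery test pulse,
#' and/or a current-injection step for excitability measurements.
#'
#' @param stimulus_times stimulus times in seconds, strictly ascending
#'   (may be empty for step-only protocols).
#' @param train_frequency optional train frequency in Hz; when given, the
#'   inter-stimulus spacing must equal `1/train_frequency` within `tol`.
#' @param recovery_interval optional recovery interval in seconds (> 0)
#'   between the last train stimulus and a test pulse.
#' @param step_onset,step_duration step timing in seconds (current clamp).
#' @param step_amplitude step amplitude in pA.
#' @param baseline_potential holding potential in mV before the step.
#' @param tol tolerance (s) for the spacing check; defaults to one sample
#'   period at 50 kHz.
#' @return an object of class `stim_protocol`.
#' @export
#' @examples
#' p <- train_protocol(40, 100)       # 40 stimuli at 100 Hz
#' pp <- paired_pulse_protocol(0.05)  # paired pulses, 50 ms ISI
stim_protocol <- function(stimulus_times = numeric(0), train_frequency = NULL,
                          recovery_interval = NULL, step_onset = NULL,
                          step_duration = NULL, step_amplitude = NULL,
                          baseline_potential = NULL, tol = 1 / 50000) {
  stimulus_times <- as.numeric(stimulus_times)
  if (length(stimulus_times) > 1 && any(diff(stimulus_times) <= 0))
    abort_fmt("stimulus_times must be strictly ascending")
  if (!is.null(train_frequency)) {
    if (!is_scalar_num(train_frequency) || train_frequency <= 0)
      abort_fmt("train_frequency must be positive")
    if (length(stimulus_times) > 1) {
      isi <- diff(stimulus_times)
      if (any(abs(isi - 1 / train_frequency) > tol))
        abort_fmt("stimulus spacing inconsistent with train_frequency")
    }
  }
  if (!is.null(recovery_interval) &&
      (!is_scalar_num(recovery_interval) || recovery_interval <= 0))
    abort_fmt("recovery_interval must be > 0")
  if (!is.null(step_onset) || !is.null(step_duration) || !is.null(step_amplitude)) {
    if (is.null(step_onset) || is.null(step_duration) || is.null(step_amplitude))
      abort_fmt("step_onset, step_duration and step_amplitude must be given together")
    if (step_duration <= 0) abort_fmt("step_duration must be > 0")
  }
  structure(
    list(stimulus_times = stimulus_times,
         train_frequency = train_frequency,
         n_stimuli = length(stimulus_times),
         recovery_interval = recovery_interval,
         step_onset = step_onset, step_duration = step_duration,
         step_amplitude = step_amplitude,
         baseline_potential = baseline_potential),
    class = "stim_protocol")
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat("<stim_protocol>")
  if (x$n_stimuli > 0)
    cat(sprintf(" %d stimuli%s", x$n_stimuli,
                if (!is.null(x$train_frequency))
                  sprintf(" at %g Hz", x$train_frequency) else ""))
  if (!is.null(x$recovery_interval))
    cat(sprintf(", recovery %g ms", 1000 * x$recovery_interval))
  if (!is.null(x$step_onset))
    cat(sprintf(", step %g pA for %g ms", x$step_amplitude,
                1000 * x$step_duration))
  cat("\n")
  invisible(x)
}

#' @rdname stim_protocol
#' @param n_stimuli number of stimuli in the train.
#' @param frequency train frequency in Hz.
#' @param start time of the first stimulus in seconds.
#' @export
train_protocol <- function(n_stimuli = 40, frequency = 100, start = 0.05,
                           recovery_interval = NULL) {
  stim_protocol(start + (seq_len(n_stimuli) - 1) / frequency,
                train_frequency = frequency,
                recovery_interval = recovery_interval)
}

#' @rdname stim_protocol
#' @param isi inter-stimulus interval in seconds (50 ms in the standard
#'   paired-pulse protocol).
#' @export
paired_pulse_protocol <- function(isi = 0.05, start = 0.05) {
  stim_protocol(c(start, start + isi))
}

#' @rdname stim_protocol
#' @param onset,duration,amplitude step onset (s), duration (s) and
#'   amplitude (pA); the canonical excitability protocol is a 200 ms step
#'   of 20-150 pA from a hyperpolarised baseline.
#' @param baseline holding potential in mV.
#' @export
step_protocol <- function(onset = 0.1, duration = 0.2, amplitude = 50,
                          baseline = -60) {
  stim_protocol(step_onset = onset, step_duration = duration,
                step_amplitude = amplitude, baseline_potential = baseline)
}
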