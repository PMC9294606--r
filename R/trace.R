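#' Uniformly sampled electrophysiological trace
#'
#' The basic container for a single continuous recording: a vector of
#' samples at a fixed sampling rate, together with the signal kind
#' (voltage-clamp current in pA or current-clamp voltage in mV) and free
#' metadata. All analysis functions in the package operate on this class.
#'
#' @param samples numeric vector of finite sample values (pA for current,
#'   mV for voltage).
#' @param sampling_rate sampling rate in Hz (> 0). Recordings digitised at
#'   50 kHz are the package default throughout.
#' @param start_time time of the first sample in seconds.
#' @param kind `"current"` or `"voltage"`; determines the unit label.
#' @param metadata named list of free-form metadata, preserved by file I/O.
#' @return an object of class `ephys_trace`.
#' @export
#' @examples
#' tr <- ephys_trace(rnorm(1000), 50000, kind = "current")
#' trace_duration(tr)
ephys_trace <- function(samples, sampling_rate, start_time = 0,
                        kind = c("current", "voltage"), metadata = list()) {
  kind <- match.arg(kind)
  samples <- as.numeric(samples)
  if (length(samples) < 1L) abort_fmt("trace must contain at least one sample")
  if (!all(is.finite(samples))) abort_fmt("trace samples must all be finite")
  if (!is_scalar_num(sampling_rate) || sampling_rate <= 0)
    abort_fmt("sampling_rate must be a positive number")
  if (!is_scalar_num(start_time)) abort_fmt("start_time must be a finite number")
  structure(
    list(samples = samples, sampling_rate = as.numeric(sampling_rate),
         start_time = as.numeric(start_time), kind = kind,
         metadata = as.list(metadata)),
    class = "ephys_trace")
}

#' @export
print.ephys_trace <- function(x, ...) {
  cat(sprintf("<ephys_trace> %s, %d samples @ %g Hz (%.4g s), unit %s\n",
              x$kind, length(x$samples), x$sampling_rate,
              trace_duration(x), trace_unit(x)))
  invisible(x)
}

#' Unit label for a trace
#' @param trace an `ephys_trace`.
#' @return `"pA"` for current traces, `"mV"` for voltage traces.
#' @export
trace_unit <- function(trace) if (trace$kind == "current") "pA" else "mV"

#' Sample times of a trace
#' @param trace an `ephys_trace`.
#' @return numeric vector of sample times in seconds.
#' @export
trace_times <- function(trace) {
  trace$start_time + (seq_along(trace$samples) - 1) / trace$sampling_rate
}

#' Duration of a trace in seconds
#' @param trace an `ephys_trace`.
#' @return duration in seconds (n samples / rate).
#' @export
trace_duration <- function(trace) length(trace$samples) / trace$sampling_rate

# index of the sample closest to time t (1-based); errors outside the trace
trace_index <- function(trace, t, clamp = FALSE) {
  i <- round((t - trace$start_time) * trace$sampling_rate) + 1
  if (clamp) return(pmin(pmax(i, 1L), length(trace$samples)))
  if (any(i < 1L | i > length(trace$samples)))
    abort_fmt("time outside trace bounds")
  as.integer(i)
}

#' Set of sweeps sharing one protocol
#'
#' Bundles repeated sweeps of the same protocol. All sweeps must share
#' sampling rate, length and kind; rate mismatches are errors, never
#' silently resampled.
#'
#' @param sweeps list of [ephys_trace()] objects (at least one).
#' @param protocol optional [stim_protocol()] shared by all sweeps.
#' @return an object of class `sweep_set`.
#' @export
sweep_set <- function(sweeps, protocol = NULL) {
  if (!is.list(sweeps) || length(sweeps) < 1L)
    abort_fmt("sweep_set needs at least one sweep")
  if (!all(vapply(sweeps, inherits, logical(1), "ephys_trace")))
    abort_fmt("all sweeps must be ephys_trace objects")
  rates <- vapply(sweeps, `[[`, numeric(1), "sampling_rate")
  lens  <- vapply(sweeps, function(s) length(s$samples), integer(1))
  kinds <- vapply(sweeps, `[[`, character(1), "kind")
  if (length(unique(rates)) != 1L) abort_fmt("sweeps differ in sampling_rate")
  if (length(unique(lens)) != 1L)  abort_fmt("sweeps differ in length")
  if (length(unique(kinds)) != 1L) abort_fmt("sweeps differ in kind")
  if (!is.null(protocol) && !inherits(protocol, "stim_protocol"))
    abort_fmt("protocol must be a stim_protocol")
  structure(list(sweeps = sweeps, protocol = protocol), class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("<sweep_set> %d sweeps of %d samples (%s)\n",
              length(x$sweeps), length(x$sweeps[[1]]$samples),
              x$sweeps[[1]]$kind))
  invisible(x)
}

#' @export
length.sweep_set <- function(x) length(x$sweeps)

#' Pointwise average of a sweep set
#'
#' Arithmetic mean across sweeps, sample by sample, as used when reporting
#' evoked responses as averages of repeated trials (typically at least 10
#' sweeps per cell). The number of sweeps averaged is recorded in the
#' output metadata.
#'
#' @param sweeps a [sweep_set()].
#' @return an `ephys_trace` with `metadata$n_averaged` set.
#' @export
average_sweeps <- function(sweeps) {
  if (!inherits(sweeps, "sweep_set")) abort_fmt("average_sweeps needs a sweep_set")
  mat <- vapply(sweeps$sweeps, `[[`, numeric(length(sweeps$sweeps[[1]]$samples)),
                "samples")
  s1 <- sweeps$sweeps[[1]]
  avg <- if (is.matrix(mat)) rowMeans(mat) else mean(mat)
  md <- s1$metadata
  md$n_averaged <- length(sweeps$sweeps)
  ephys_trace(avg, s1$sampling_rate, s1$start_time, s1$kind, md)
}
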