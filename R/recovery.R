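#' Recovery-from-depression curve
#'
#' Converts test-pulse amplitudes measured at different intervals after a
#' depleting train into recovery ratios: test amplitude over the first
#' amplitude of the train.
#'
#' @param train_amps amplitude vector of the depleting train (pA);
#'   `train_amps[1]` must be > 0.
#' @param tests data frame with columns `interval` (s) and `amplitude`
#'   (pA), one row per recovery test pulse.
#' @return a `recovery_curve` data frame with columns `interval` and
#'   `ratio`, sorted by interval.
#' @export
recovery_ratios <- function(train_amps, tests) {
  if (length(train_amps) < 1L || !is.finite(train_amps[1]) || train_amps[1] <= 0)
    abort_fmt("first train amplitude must be > 0")
  if (!is.data.frame(tests) || !all(c("interval", "amplitude") %in% names(tests)))
    abort_fmt("tests must be a data frame with interval and amplitude columns")
  ord <- order(tests$interval)
  out <- data.frame(interval = tests$interval[ord],
                    ratio = tests$amplitude[ord] / train_amps[1])
  class(out) <- c("recovery_curve", "data.frame")
  out
}

#' Exponential fit of a recovery curve
#'
#' Least-squares fit of `R(t) = plateau - (plateau - floor) *
#' exp(-t / tau)`. This single-exponential summary is an extension beyond
#' the raw ratio-versus-interval curve: the depletion model's capped
#' linear refill is not exactly exponential, so residuals are reported
#' and should be inspected.
#'
#' @param curve a `recovery_curve` (or data frame with `interval`,
#'   `ratio`), at least 4 distinct intervals.
#' @param plateau_max upper bound for the fitted plateau.
#' @return list with `tau_recovery` (s), `floor`, `plateau`, `residuals`,
#'   `converged`, `degenerate`.
#' @export
fit_recovery <- function(curve, plateau_max = 1.2) {
  if (length(unique(curve$interval)) < 4L)
    abort_fmt("recovery fit needs at least 4 distinct intervals")
  if (stats::var(curve$ratio) < 1e-12)
    return(list(tau_recovery = NA_real_, floor = NA_real_, plateau = NA_real_,
                residuals = curve$ratio - mean(curve$ratio),
                converged = FALSE, degenerate = TRUE))
  start <- list(plateau = 1, floor = curve$ratio[1],
                tau = stats::median(curve$interval))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      ratio ~ plateau - (plateau - floor) * exp(-interval / tau),
      data = curve, start = start,
      lower = c(plateau = 0, floor = 0, tau = 1e-4),
      upper = c(plateau = plateau_max, floor = plateau_max, tau = 100),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(tau_recovery = NA_real_, floor = NA_real_, plateau = NA_real_,
                residuals = rep(NA_real_, nrow(curve)),
                converged = FALSE, degenerate = FALSE))
  cf <- stats::coef(fit)
  list(tau_recovery = unname(cf["tau"]), floor = unname(cf["floor"]),
       plateau = unname(cf["plateau"]), residuals = stats::residuals(fit),
       converged = TRUE, degenerate = FALSE)
}

#' Measure a recovery curve from rendered sweeps
#'
#' Applies [measure_train_amplitudes()] to a train-plus-test-pulse sweep
#' for each recovery interval and assembles the ratio curve.
#'
#' @param sweeps_by_interval named list: for each interval (names in
#'   seconds), an averaged `ephys_trace` whose protocol is the train plus
#'   one test stimulus at `last train stimulus + interval`.
#' @param protocol the depleting train protocol (without the test pulse).
#' @return a `recovery_curve` data frame.
#' @export
analyze_recovery <- function(sweeps_by_interval, protocol) {
  intervals <- as.numeric(names(sweeps_by_interval))
  if (anyNA(intervals)) abort_fmt("list names must be the intervals in seconds")
  last_t <- max(protocol$stimulus_times)
  rows <- lapply(seq_along(intervals), function(i) {
    tr <- sweeps_by_interval[[i]]
    full <- stim_protocol(c(protocol$stimulus_times, last_t + intervals[i]))
    amps <- measure_train_amplitudes(tr, full)
    n <- length(amps)
    data.frame(interval = intervals[i], amplitude = amps[n],
               first = amps[1])
  })
  tab <- do.call(rbind, rows)
  ord <- order(tab$interval)
  out <- data.frame(interval = tab$interval[ord],
                    ratio = (tab$amplitude / tab$first)[ord])
  class(out) <- c("recovery_curve", "data.frame")
  out
}
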