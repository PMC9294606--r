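# Plain-text trace and sweep-container I/O.
#
# Dialect: delimited text with '#'-prefixed "key: value" header lines
# (sampling_rate, kind, units, start_time, plus free metadata), followed by
# one sample per row. Values are written with 17 significant digits so a
# write/read round trip is lossless for doubles.

required_header <- c("sampling_rate", "kind")

#' Write a trace to a self-describing text file
#'
#' @param trace an [ephys_trace()].
#' @param path destination path.
#' @param dialect `"tsv"` or `"csv"`; controls the delimiter used when a
#'   time column is written.
#' @param time_column also write a time column (s) before the samples.
#' @return invisibly, `path`.
#' @export
write_trace <- function(trace, path, dialect = c("tsv", "csv"),
                        time_column = FALSE) {
  dialect <- match.arg(dialect)
  if (!inherits(trace, "ephys_trace")) abort_fmt("write_trace needs an ephys_trace")
  sep <- if (dialect == "tsv") "\t" else ","
  hdr <- c(
    sprintf("# sampling_rate: %.17g", trace$sampling_rate),
    sprintf("# kind: %s", trace$kind),
    sprintf("# units: %s", trace_unit(trace)),
    sprintf("# start_time: %.17g", trace$start_time))
  meta <- trace$metadata
  meta <- meta[vapply(meta, function(v)
    is.atomic(v) && length(v) == 1L, logical(1))]
  hdr <- c(hdr, vapply(names(meta), function(k)
    sprintf("# %s: %s", k, format(meta[[k]], digits = 17)), character(1)))
  vals <- sprintf("%.17g", trace$samples)
  if (time_column)
    vals <- paste(sprintf("%.17g", trace_times(trace)), vals, sep = sep)
  con <- file(path, "wb")  # binary mode: LF endings on every platform
  on.exit(close(con))
  writeLines(c(hdr, vals), con, sep = "\n")
  invisible(path)
}

#' Read a trace written by [write_trace()]
#'
#' The header must declare at least `sampling_rate` and `kind`; any other
#' header keys are restored into the trace metadata. If the file carries a
#' time column it must be uniform and ascending at the declared rate.
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"csv"`.
#' @return an [ephys_trace()].
#' @export
read_trace <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort_fmt("file not found: %s", path)
  sep <- if (dialect == "tsv") "\t" else ","
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  hdr_lines <- lines[is_hdr]
  body <- lines[!is_hdr & nzchar(lines)]
  kv <- list()
  for (ln in hdr_lines) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+?)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) kv[[m[2]]] <- m[3]
  }
  missing <- setdiff(required_header, names(kv))
  if (length(missing))
    abort_fmt("trace header missing required field(s): %s",
              paste(missing, collapse = ", "))
  rate <- suppressWarnings(as.numeric(kv$sampling_rate))
  if (!is_scalar_num(rate)) abort_fmt("trace header has ambiguous sampling_rate")
  kind <- kv$kind
  if (!kind %in% c("current", "voltage"))
    abort_fmt("trace header has unknown kind '%s'", kind)
  start_time <- if (!is.null(kv$start_time)) as.numeric(kv$start_time) else 0
  fields <- strsplit(body, sep, fixed = TRUE)
  ncol <- unique(lengths(fields))
  if (length(ncol) != 1L) abort_fmt("inconsistent column count in trace body")
  if (ncol == 1L) {
    samples <- as.numeric(body)
  } else if (ncol == 2L) {
    tv <- vapply(fields, function(f) as.numeric(f), numeric(2))
    tt <- tv[1, ]; samples <- tv[2, ]
    if (any(diff(tt) <= 0)) abort_fmt("non-monotonic time column")
    if (max(abs(diff(tt) - 1 / rate)) > 0.5 / rate)
      abort_fmt("non-uniform time column")
    start_time <- tt[1]
  } else abort_fmt("trace body must have 1 or 2 columns")
  if (anyNA(samples)) abort_fmt("non-numeric sample values in trace body")
  meta_keys <- setdiff(names(kv), c(required_header, "units", "start_time"))
  meta <- lapply(kv[meta_keys], utils::type.convert, as.is = TRUE)
  ephys_trace(samples, rate, start_time, kind, meta)
}

#' Write a sweep set as a manifest-based directory container
#'
#' One trace file per sweep plus a `manifest.yaml` describing the sweeps
#' and (optionally) the shared protocol.
#'
#' @param sweeps a [sweep_set()].
#' @param dir destination directory (created if needed).
#' @param dialect passed to [write_trace()].
#' @return invisibly, `dir`.
#' @export
write_sweep_set <- function(sweeps, dir, dialect = "tsv") {
  if (!inherits(sweeps, "sweep_set")) abort_fmt("write_sweep_set needs a sweep_set")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("sweep_%03d.%s", seq_along(sweeps$sweeps), dialect)
  for (i in seq_along(sweeps$sweeps))
    write_trace(sweeps$sweeps[[i]], file.path(dir, files[i]), dialect)
  manifest <- list(container = "sweep_set", n_sweeps = length(sweeps$sweeps),
                   dialect = dialect, files = files)
  if (!is.null(sweeps$protocol)) {
    p <- sweeps$protocol
    manifest$protocol <- Filter(Negate(is.null), list(
      stimulus_times = p$stimulus_times, train_frequency = p$train_frequency,
      recovery_interval = p$recovery_interval, step_onset = p$step_onset,
      step_duration = p$step_duration, step_amplitude = p$step_amplitude,
      baseline_potential = p$baseline_potential))
  }
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"),
                   precision = 17)
  invisible(dir)
}

#' Read a sweep-set container written by [write_sweep_set()]
#' @param dir container directory.
#' @return a [sweep_set()].
#' @export
read_sweep_set <- function(dir) {
  mf <- file.path(dir, "manifest.yaml")
  if (!file.exists(mf)) abort_fmt("no manifest.yaml in %s", dir)
  manifest <- yaml::read_yaml(mf)
  sweeps <- lapply(manifest$files, function(f)
    read_trace(file.path(dir, f), manifest$dialect))
  protocol <- NULL
  if (!is.null(manifest$protocol)) {
    pr <- manifest$protocol
    protocol <- stim_protocol(
      stimulus_times = if (is.null(pr$stimulus_times)) numeric(0) else
        unlist(pr$stimulus_times),
      train_frequency = pr$train_frequency,
      recovery_interval = pr$recovery_interval,
      step_onset = pr$step_onset, step_duration = pr$step_duration,
      step_amplitude = pr$step_amplitude,
      baseline_potential = pr$baseline_potential)
  }
  sweep_set(sweeps, protocol)
}
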