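# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, then restores the
#' previous RNG state so generators behave as pure functions of
#' (parameters, seed) without disturbing the caller's random stream.
#'
#' @param seed integer seed, or NULL to use the current stream.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# stop() with a consistent prefix so callers can match error classes by text
abort_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Linear interpolation of the time at which y crosses `level` between
# samples i and i+1 of (t, y). Assumes y[i] and y[i+1] bracket `level`.
interp_crossing <- function(t, y, i, level) {
  dy <- y[i + 1L] - y[i]
  if (dy == 0) return(t[i])
  t[i] + (level - y[i]) / dy * (t[i + 1L] - t[i])
}

# Gaussian recording noise, band-limited to emulate the acquisition
# chain's low-pass filter (recordings are typically filtered at 5 kHz
# before 50 kHz digitisation). Rescaled so the sample SD equals `sd`.
band_limited_noise <- function(n, sd, rate, bandwidth = 5000) {
  nz <- stats::rnorm(n)
  if (!is.null(bandwidth) && is.finite(bandwidth) && bandwidth < rate / 2) {
    bf <- signal::butter(4, bandwidth / (rate / 2))
    nz <- signal::filtfilt(bf, nz)
    nz <- nz / stats::sd(nz)
  }
  sd * nz
}

# Ordinary least squares y ~ x returning c(intercept, slope, r2).
ols_line <- function(x, y) {
  fit <- stats::lm.fit(cbind(1, x), y)
  b <- unname(fit$coefficients)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  c(intercept = b[1L], slope = b[2L], r2 = r2)
}
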