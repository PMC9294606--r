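#' Two-group comparison by unpaired t-test
#'
#' Two-tailed unpaired Student's t-test (pooled variance, df = n_a + n_b
#' - 2) as the default group comparison; Welch's unequal-variance
#' variant is available by flag. Groups with zero pooled variance and
#' equal means return t = 0, p = 1 rather than erroring.
#'
#' @param a,b numeric vectors (each n >= 2).
#' @param variant `"student"` (pooled variance) or `"welch"`.
#' @param labels length-2 character vector of group labels.
#' @return a `group_comparison` list: per-group `n`, `mean`, `sem`
#'   (SD/sqrt(n)), plus `t`, `df`, `p`.
#' @export
#' @examples
#' group_compare(c(1, 2, 3), c(4, 5, 6))
group_compare <- function(a, b, variant = c("student", "welch"),
                          labels = c("a", "b")) {
  variant <- match.arg(variant)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L)
    abort_fmt("each group needs at least 2 finite values")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    t_stat <- if (mean(a) == mean(b)) 0 else Inf * sign(mean(a) - mean(b))
    df <- length(a) + length(b) - 2
    p <- if (t_stat == 0) 1 else 0
  } else {
    tst <- stats::t.test(a, b, var.equal = (variant == "student"))
    t_stat <- unname(tst$statistic)
    df <- unname(tst$parameter)
    p <- tst$p.value
  }
  structure(list(
    labels = labels, variant = variant,
    n = c(length(a), length(b)), mean = c(mean(a), mean(b)),
    sem = c(stats::sd(a) / sqrt(length(a)), stats::sd(b) / sqrt(length(b))),
    t = t_stat, df = df, p = p), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> (%s t-test)\n", x$variant))
  for (i in 1:2)
    cat(sprintf("  %s: %.4g +/- %.3g (n = %d)\n",
                x$labels[i], x$mean[i], x$sem[i], x$n[i]))
  cat(sprintf("  t(%g) = %.4g, two-tailed p = %.4g\n", x$df, x$t, x$p))
  invisible(x)
}

#' @export
as.data.frame.group_comparison <- function(x, ...) {
  data.frame(group_a = x$labels[1], group_b = x$labels[2],
             n_a = x$n[1], n_b = x$n[2], mean_a = x$mean[1],
             mean_b = x$mean[2], sem_a = x$sem[1], sem_b = x$sem[2],
             t = x$t, df = x$df, p = x$p)
}
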