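# Independent oracles used across the test files. These deliberately use
# textbook formulas and explicit loops, not the package's own code paths.

# textbook OLS: slope/intercept from the raw sums
ols_oracle <- function(x, y) {
  n <- length(x)
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  sxx <- sum(x^2) - sum(x)^2 / n
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  c(intercept = intercept, slope = slope)
}

# textbook pooled-variance two-sample t statistic and two-tailed p
t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  c(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# explicit-loop depletion recursion (deterministic, uncapped)
depletion_oracle <- function(n0, p, repl_per_isi, k) {
  n <- n0
  out <- numeric(k)
  for (i in seq_len(k)) {
    rel <- p * n
    out[i] <- rel
    n <- n - rel + repl_per_isi
  }
  out / out[1]
}

# greedy matching of detected event times against ground truth
match_events <- function(truth, detected, tol = 0.002) {
  used <- rep(FALSE, length(detected))
  tp <- 0L
  for (t in truth) {
    j <- which(!used & abs(detected - t) <= tol)
    if (length(j)) { used[j[1]] <- TRUE; tp <- tp + 1L }
  }
  c(recall = tp / length(truth), precision = tp / length(detected))
}

expect_rel_error <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
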