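# From-scratch statistical oracles: sums, pairwise counts and the
# incomplete-beta CDF only — independent of stats::t.test/aov/cor.test
# and of the package's own code paths.

oracle_t2 <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  df <- nx + ny - 2
  c(t = t, p = stats::pbeta(df / (df + t^2), df / 2, 1 / 2))
}

oracle_f <- function(groups) {
  v <- unlist(groups)
  gm <- mean(v)
  ssb <- sum(lengths(groups) * (vapply(groups, mean, 0) - gm)^2)
  ssw <- sum(unlist(lapply(groups, function(x) (x - mean(x))^2)))
  df1 <- length(groups) - 1; df2 <- length(v) - length(groups)
  f <- (ssb / df1) / (ssw / df2)
  c(f = f, p = stats::pbeta(df2 / (df2 + df1 * f), df2 / 2, df1 / 2))
}

# literal step-up walk through the ordered p-values
oracle_bh <- function(p) {
  n <- length(p); o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

oracle_pearson <- function(x, y) {
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  df <- length(x) - 2
  t <- r * sqrt(df / (1 - r^2))
  c(r = r, p = stats::pbeta(df / (df + t^2), df / 2, 1 / 2))
}
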