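# Independent brute-force oracles used to freeze expected values. These
# deliberately re-derive each statistic from first principles and never
# call the package code paths they check.

# textbook Pearson correlation: covariance over product of sample sds
pearson_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  cov <- sum((x - mx) * (y - my)) / (n - 1)
  sx <- sqrt(sum((x - mx)^2) / (n - 1))
  sy <- sqrt(sum((y - my)^2) / (n - 1))
  cov / (sx / 1) / sy
}

# hypergeometric upper tail P(X >= k) by explicit choose() summation
hyper_upper_oracle <- function(k, K, N, n) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Benjamini-Hochberg step-up, written as the literal procedure
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  # enforce monotonicity from the largest rank down
  if (n > 1) {
    for (i in (n - 1):1) ranked[i] <- min(ranked[i], ranked[i + 1])
  }
  out <- numeric(n)
  out[o] <- pmin(ranked, 1)
  out
}

# Simes combination p-value of a set of raw p-values
simes_p <- function(p) {
  ps <- sort(p)
  min(length(p) * ps / seq_along(ps))
}

# Hommel adjusted p by exhaustive closed testing: for each hypothesis,
# the max Simes p over all subsets containing it
hommel_oracle <- function(p) {
  n <- length(p)
  adj <- numeric(n)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  for (i in seq_len(n)) {
    mx <- 0
    for (r in seq_len(nrow(subsets))) {
      s <- unlist(subsets[r, ])
      if (!s[i]) next
      mx <- max(mx, simes_p(p[s]))
    }
    adj[i] <- min(1, mx)
  }
  adj
}

# two-sample KS statistic from explicit ECDF evaluation
ks_D_oracle <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  Fx <- vapply(pts, function(t) mean(x <= t), numeric(1))
  Fy <- vapply(pts, function(t) mean(y <= t), numeric(1))
  max(abs(Fx - Fy))
}

# exact two-sided two-sample KS p by enumerating all label assignments
ks_p_oracle <- function(x, y) {
  m <- length(x)
  pooled <- c(x, y)
  d_obs <- ks_D_oracle(x, y)
  idx <- utils::combn(length(pooled), m)
  hits <- apply(idx, 2, function(ii) {
    ks_D_oracle(pooled[ii], pooled[-ii]) >= d_obs - 1e-12
  })
  mean(hits)
}

# chi-square upper tail by adaptive quadrature of the density
chisq_tail_oracle <- function(x, df) {
  stats::integrate(function(t) stats::dchisq(t, df), x, Inf,
                   rel.tol = 1e-13, abs.tol = 1e-300)$value
}
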