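# Independent brute-force oracles used across the suite. These never call
# into the package code paths they check.

# Benjamini-Hochberg step-up computed directly from the definition:
# q_i = min_{j >= rank(i)} p_(j) * n / j
bh_stepup_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- numeric(n)
  sorted <- p[ord]
  for (i in seq_len(n)) {
    q[i] <- min(sorted[i:n] * n / (i:n))
  }
  pmin(q, 1)[order(ord)]
}

# Upper-tail hypergeometric probability by exhaustive enumeration of the
# overlap distribution (universe N, set K, draw k, observed overlap x).
hyper_tail_oracle <- function(x, N, K, k) {
  support <- 0:min(K, k)
  probs <- choose(K, support) * choose(N - K, k - support) / choose(N, k)
  sum(probs[support >= x])
}

# One-sided (greater) Fisher p for a 2x2 via the hypergeometric tail.
fisher_greater_oracle <- function(tab) {
  hyper_tail_oracle(tab[1, 1], sum(tab), sum(tab[1, ]), sum(tab[, 1]))
}

# Closed-form pooled-variance two-sample t-test.
pooled_t_oracle <- function(values, status) {
  g1 <- values[status == 1]
  g0 <- values[status == 0]
  df <- length(g1) + length(g0) - 2
  sp2 <- (sum((g1 - mean(g1))^2) + sum((g0 - mean(g0))^2)) / df
  se <- sqrt(sp2 * (1 / length(g0) + 1 / length(g1)))
  t <- (mean(g1) - mean(g0)) / se
  list(estimate = mean(g1) - mean(g0), t = t,
       p = 2 * pt(-abs(t), df), df = df)
}

# Simple-regression slope and its standard error from the closed form.
ols_slope_oracle <- function(x, y) {
  xc <- x - mean(x)
  slope <- sum(xc * y) / sum(xc^2)
  resid <- y - mean(y) - slope * xc
  se <- sqrt(sum(resid^2) / (length(x) - 2) / sum(xc^2))
  list(slope = slope, se = se)
}

# Permutation test of the indirect effect a*b: permutes the mediator
# residual structure by shuffling cis within the sample set, keeping
# status and trans fixed.
indirect_permutation_oracle <- function(status, cis, trans, n_perm = 2000,
                                        seed = 99) {
  set.seed(seed)
  sc <- status - mean(status)
  sxx <- sum(sc^2)
  ab_of <- function(ci) {
    cc <- ci - mean(ci)
    a <- sum(sc * cc) / sxx
    det2 <- sxx * sum(cc^2) - sum(sc * cc)^2
    tc <- trans - mean(trans)
    b <- (sxx * sum(cc * tc) - sum(sc * cc) * sum(sc * tc)) / det2
    a * b
  }
  obs <- ab_of(cis)
  null_ab <- replicate(n_perm, ab_of(sample(cis)))
  mean(abs(null_ab) >= abs(obs))
}
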