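# Independent oracles used to freeze expected values. These deliberately use
# brute force / direct definitions and never call the package code paths (or
# the stats routines) they are checking.

# AUC by exhaustive pair comparison: (wins + half-ties) / (n_a * n_b)
oracle_auc <- function(a, b) {
  wins <- ties <- 0
  for (x in a) for (y in b) {
    if (x > y) wins <- wins + 1
    else if (x == y) ties <- ties + 1
  }
  (wins + ties / 2) / (length(a) * length(b))
}

# Benjamini-Hochberg step-up walked by hand on the sorted p-values
oracle_bh <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- 0
  for (i in seq_len(m)) if (!is.na(ps[i]) && ps[i] <= i / m * alpha) k <- i
  rej <- rep(FALSE, m)
  if (k > 0) rej[ord[seq_len(k)]] <- TRUE
  rej
}

# two-sided exact binomial p (null 1/2) by direct summation of all outcomes
# whose probability does not exceed the observed one (minimum-likelihood rule)
oracle_binom_p <- function(k, n) {
  probs <- choose(n, 0:n) / 2^n
  sum(probs[probs <= probs[k + 1] * (1 + 1e-7)])
}

# inhomogeneous Poisson sampler for piecewise-constant rates, built from
# independent per-segment homogeneous draws (time-rescaling equivalent);
# segments: rate[i] on [breaks[i], breaks[i+1])
oracle_piecewise_poisson <- function(rates, breaks) {
  out <- numeric(0)
  for (i in seq_along(rates)) {
    len <- breaks[i + 1] - breaks[i]
    n <- rpois(1, rates[i] * len)
    if (n > 0) out <- c(out, runif(n, breaks[i], breaks[i + 1]))
  }
  sort(out)
}
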