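# Independent oracles used across the suite.

# pmf of the rounded, redraw-truncated normal clutch size (support >= 1)
clutch_size_pmf <- function(mu = 100.58, sigma = 22.61,
                            smax = ceiling(mu + 8 * sigma)) {
  s <- seq_len(smax)
  p <- pnorm(s + 0.5, mu, sigma) - pnorm(pmax(s - 0.5, 0.5), mu, sigma)
  p / (1 - pnorm(0.5, mu, sigma))
}

# P(sample of min(n, size) eggs contains every father), averaged over the
# clutch-size distribution; closed form per size via inclusion-exclusion
integrated_identify_all <- function(weights, n, mu = 100.58, sigma = 22.61) {
  pmf <- clutch_size_pmf(mu, sigma)
  ps <- vapply(seq_along(pmf), function(s) {
    analytic_identify_all_probability(weights, n, s)
  }, numeric(1))
  sum(pmf * ps)
}

# brute-force enumeration over all label sequences of length m (tiny cases
# only); deliberately independent of the inclusion-exclusion path
brute_force_identify_all <- function(weights, m) {
  f <- length(weights)
  labs <- as.matrix(expand.grid(rep(list(seq_len(f)), m)))
  pr <- apply(labs, 1L, function(x) prod(weights[x]))
  all_seen <- apply(labs, 1L, function(x) length(unique(x)) == f)
  sum(pr[all_seen])
}

# mean of a normal rounded to integer and redrawn while < 1 (closed form,
# rounding bias negligible): truncated-normal mean above 0.5
truncated_count_mean <- function(mu, sigma) {
  a <- (0.5 - mu) / sigma
  mu + sigma * dnorm(a) / (1 - pnorm(a))
}
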