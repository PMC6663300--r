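# Shared fixture builders; everything is generated in code at test time.

# Correlated bivariate Gaussian draw with correlation rho.
rbvn <- function(m, rho, seed = NULL) {
  draw <- function() {
    z <- matrix(stats::rnorm(2 * m), ncol = 2)
    z %*% chol(matrix(c(1, rho, rho, 1), 2))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Two-node ground truth with a single link 1 -> 2 at a given lag.
two_node_net <- function(lag = 2L, weight = 0.4, beta = 0.5) {
  adj <- matrix(FALSE, 2, 2); adj[1, 2] <- TRUE
  net <- assign_couplings(adj, beta = beta, total_cross = weight, seed = 1)
  net$lags[1, 2] <- as.integer(lag)
  net
}

# Brute-force Benjamini-Hochberg step-up: reject H(1)..H(k*) where k* is the
# largest k with p(k) <= k q / m.
bh_oracle <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- which(ps <= seq_len(m) * q / m)
  keep <- logical(m)
  if (length(k) > 0) keep[ord[seq_len(max(k))]] <- TRUE
  keep
}
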