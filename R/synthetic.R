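#' Directed Erdos-Renyi adjacency matrix
#'
#' Samples a directed random graph in which every ordered off-diagonal pair
#' is a link independently with probability `p` (no self-links; self-dynamics
#' enter through the autoregressive coefficient instead). With `p = 3/N` the
#' expected in-degree is `3 (N - 1) / N`, i.e. about 3 links per node for the
#' network sizes used in validation.
#'
#' @param N Number of nodes (>= 2).
#' @param p Link probability in `[0, 1]`.
#' @param seed Optional seed for reproducibility.
#' @return `N x N` logical matrix; `[i, j]` is `TRUE` for a link i -> j.
#' @export
erdos_renyi_digraph <- function(N, p, seed = NULL) {
  stopifnot(N >= 2, p >= 0, p <= 1)
  draw <- function() {
    g <- igraph::sample_gnp(N, p, directed = TRUE, loops = FALSE)
    adj <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE)) > 0
    dimnames(adj) <- NULL
    adj
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Assign coupling weights and lags to a directed network
#'
#' Turns an adjacency matrix into a fully parameterised ground-truth system:
#' every link receives a single lag drawn uniformly from `lag_range`, the
#' cross-coupling weights into each target are uniform and normalised so they
#' sum to `total_cross` (so a target with d parents gets `total_cross / d`
#' per link), and every node has self-coupling `beta` at lag 1. These are the
#' conditions under which the stochastic dynamics stay stable and stationary.
#'
#' @param adjacency Logical or 0/1 matrix, `[source, target]` orientation.
#' @param beta Self-coupling coefficient (lag 1) for every node.
#' @param total_cross Sum of cross-coupling weights into each connected target.
#' @param lag_range Integer vector of admissible lags.
#' @param seed Optional seed for the lag draw.
#' @return Object of class `ground_truth_network`: list with `N`,
#'   `adjacency`, `lags` (0 where no link), `weights`, `beta`, `lag_range`.
#' @export
assign_couplings <- function(adjacency, beta = 0.5, total_cross = 0.4,
                             lag_range = 1:5, seed = NULL) {
  adjacency <- adjacency > 0
  N <- nrow(adjacency)
  stopifnot(ncol(adjacency) == N, !any(diag(adjacency)))
  build <- function() {
    lags <- matrix(0L, N, N)
    nlinks <- sum(adjacency)
    lags[adjacency] <- sample(lag_range, nlinks, replace = TRUE)
    weights <- matrix(0, N, N)
    for (j in seq_len(N)) {
      d <- sum(adjacency[, j])
      if (d > 0) weights[adjacency[, j], j] <- total_cross / d
    }
    structure(list(N = N, adjacency = adjacency, lags = lags,
                   weights = weights, beta = rep(beta, N),
                   lag_range = as.integer(lag_range)),
              class = "ground_truth_network")
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' @export
print.ground_truth_network <- function(x, ...) {
  cat(sprintf("ground-truth network: %d nodes, %d directed links, beta = %g\n",
              x$N, sum(x$adjacency), x$beta[1]))
  invisible(x)
}

# Per-lag coefficient matrices A_l with A_l[target, source]; the
# self-coupling beta sits on the diagonal of A_1.
coefficient_matrices <- function(net) {
  L <- max(1L, net$lags)
  A <- lapply(seq_len(L), function(l) {
    a <- matrix(0, net$N, net$N)
    sel <- which(net$adjacency & net$lags == l, arr.ind = TRUE)
    if (nrow(sel) > 0)
      a[cbind(sel[, 2], sel[, 1])] <- net$weights[sel]
    a
  })
  diag(A[[1]]) <- diag(A[[1]]) + net$beta
  A
}

#' Companion-matrix spectral radius of the linear system
#'
#' Recasts the lag-structured linear system (self-coupling at lag 1,
#' cross-couplings at their assigned lags) as a first-order system via the
#' `N L x N L` companion matrix and returns its largest absolute eigenvalue.
#' A radius below 1 certifies stability and stationarity of the
#' autoregressive dynamics.
#'
#' @param net A `ground_truth_network`.
#' @return Spectral radius (nonnegative numeric).
#' @export
companion_spectral_radius <- function(net) {
  A <- coefficient_matrices(net)
  L <- length(A); N <- net$N
  comp <- matrix(0, N * L, N * L)
  for (l in seq_len(L))
    comp[seq_len(N), (l - 1) * N + seq_len(N)] <- A[[l]]
  if (L > 1)
    comp[N + seq_len(N * (L - 1)), seq_len(N * (L - 1))] <-
      diag(N * (L - 1))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

simulate_core <- function(net, T, R, noise_sd, burn_in, seed, step_fun, init_fun) {
  A <- coefficient_matrices(net)
  L <- length(A); N <- net$N
  total <- T + burn_in
  run_one <- function() {
    Y <- matrix(0, total + L, N)
    Y[seq_len(L), ] <- init_fun(L, N)
    for (t in (L + 1):(total + L)) {
      a <- numeric(N)
      for (l in seq_len(L)) a <- a + A[[l]] %*% Y[t - l, ]
      Y[t, ] <- step_fun(as.numeric(a), stats::rnorm(N, 0, noise_sd))
    }
    Y[(L + burn_in + 1):(L + total), , drop = FALSE]
  }
  sim <- function() {
    out <- array(NA_real_, c(T, N, R))
    for (r in seq_len(R)) out[, , r] <- run_one()
    out
  }
  if (is.null(seed)) sim() else withr::with_seed(seed, sim())
}

#' Simulate a vector autoregressive process on a network
#'
#' Iterates the stochastic recurrence
#' \deqn{Y_t = \beta Y_{t-1} + \sum_{X \in pa(Y)} \alpha_X X_{t-l_X} + \eta_t}
#' for every node, with uncorrelated Gaussian noise of mean 0 and standard
#' deviation `noise_sd`. Initial conditions are zero; `burn_in` samples are
#' discarded so the returned series is (weak-sense) stationary. The system
#' must be stable: simulation refuses to run when the companion spectral
#' radius is 0.999 or larger.
#'
#' @param net A `ground_truth_network`.
#' @param T Number of retained time samples.
#' @param R Number of replications (trials).
#' @param noise_sd Innovation standard deviation (default 0.1).
#' @param burn_in Discarded initial samples (default 1000).
#' @param seed Optional seed; a fixed seed reproduces the array bit-exactly.
#' @return `T x N x R` numeric array.
#' @export
simulate_var <- function(net, T, R = 1L, noise_sd = 0.1, burn_in = 1000L,
                         seed = NULL) {
  stopifnot(T >= 1, R >= 1, noise_sd >= 0)
  rho <- companion_spectral_radius(net)
  if (rho >= 0.999)
    stop(sprintf("unstable system: companion spectral radius %.4f >= 0.999", rho))
  simulate_core(net, T, R, noise_sd, burn_in, seed,
                step_fun = function(a, eta) a + eta,
                init_fun = function(L, N) matrix(0, L, N))
}

#' Simulate coupled logistic maps on a network
#'
#' Each node computes the weighted input
#' \eqn{a_t = \beta Y_{t-1} + \sum \alpha_X X_{t-l_X}} and maps it through
#' the fully chaotic logistic map (r = 4) before adding Gaussian noise and
#' wrapping into the unit interval:
#' \deqn{Y_t = \left(4 a_t (1 - a_t) + \eta_t\right) \bmod 1.}
#' The modulo-1 operation keeps every value in `[0, 1)`. Initial conditions
#' are uniform on (0, 1); `burn_in` samples are discarded. The stationary
#' marginals are strongly non-Gaussian, which is the regime where the
#' nearest-neighbour estimator outperforms the Gaussian one.
#'
#' @inheritParams simulate_var
#' @return `T x N x R` numeric array with values in `[0, 1)`.
#' @export
simulate_clm <- function(net, T, R = 1L, noise_sd = 0.1, burn_in = 1000L,
                         seed = NULL) {
  stopifnot(T >= 1, R >= 1, noise_sd >= 0)
  simulate_core(net, T, R, noise_sd, burn_in, seed,
                step_fun = function(a, eta) (4 * a * (1 - a) + eta) %% 1,
                init_fun = function(L, N) matrix(stats::runif(L * N), L, N))
}

#' Generate a parameterised random network in one call
#'
#' Convenience wrapper: ER adjacency at link probability `p` plus the
#' standard coupling assignment.
#'
#' @inheritParams erdos_renyi_digraph
#' @inheritParams assign_couplings
#' @return A `ground_truth_network`.
#' @export
random_var_network <- function(N, p = 3 / N, beta = 0.5, total_cross = 0.4,
                               lag_range = 1:5, seed = NULL) {
  gen <- function() assign_couplings(erdos_renyi_digraph(N, p),
                                     beta = beta, total_cross = total_cross,
                                     lag_range = lag_range)
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Empty (null) network of N isolated nodes
#'
#' Ground truth with no links and only self-dynamics; every link inferred
#' from data simulated on it is a false positive by construction.
#'
#' @param N Number of nodes.
#' @param beta Self-coupling.
#' @return A `ground_truth_network` with empty adjacency.
#' @export
empty_network <- function(N, beta = 0.5) {
  assign_couplings(matrix(FALSE, N, N), beta = beta)
}
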