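#' Gaussian conditional mutual information
#'
#' Estimates I(X; Y | Z) in nats under a joint-Gaussian model, from the
#' log-determinants of the empirical covariance matrices:
#' \deqn{I = \frac{1}{2}\left[\ln|\Sigma_{XZ}| + \ln|\Sigma_{YZ}|
#'   - \ln|\Sigma_{XYZ}| - \ln|\Sigma_{Z}|\right].}
#' With an empty conditioning set this reduces to the Gaussian mutual
#' information \eqn{-\frac{1}{2}\ln(1-\rho^2)}. Covariances use mean removal
#' and 1/M normalisation; the normalisation constant cancels across the four
#' terms. The raw estimate is returned without clipping, so small negative
#' values are possible at finite sample size; significance testing, not the
#' sign, decides whether a contribution is real.
#'
#' @param x Numeric vector or single-column matrix.
#' @param y Numeric vector or single-column matrix.
#' @param z Optional numeric vector or matrix of conditioning variables
#'   (columns are variables); `NULL` for unconditional mutual information.
#' @return Object of class `cmi_estimate`: list with `value` (nats),
#'   `estimator`, `M` (sample count), and dimensions `dx`, `dy`.
#' @examples
#' s <- matrix(c(1, 0.6, 0.6, 1), 2)
#' xy <- matrix(rnorm(2000), ncol = 2) %*% chol(s)
#' gaussian_cmi(xy[, 1], xy[, 2])$value  # near -0.5 * log(1 - 0.36)
#' @export
gaussian_cmi <- function(x, y, z = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  z <- if (is.null(z) || length(z) == 0L) NULL else as.matrix(z)
  m <- nrow(x)
  if (nrow(y) != m || (!is.null(z) && nrow(z) != m))
    stop("x, y and z must have the same number of rows")
  dat <- cbind(x, y, if (!is.null(z)) z)
  if (!all(is.finite(dat))) stop("non-finite values in input")
  nv <- ncol(dat)
  if (m < nv + 2L) stop("need at least ", nv + 2L, " samples for ", nv, " variables")
  sigma <- crossprod(scale(dat, center = TRUE, scale = FALSE)) / m
  ix <- seq_len(ncol(x))
  iy <- ncol(x) + seq_len(ncol(y))
  iz <- if (is.null(z)) integer(0) else ncol(x) + ncol(y) + seq_len(ncol(z))
  value <- gaussian_cmi_from_cov(sigma, ix, iy, iz)
  structure(list(value = value, estimator = "gaussian", M = m,
                 dx = ncol(x), dy = ncol(y)),
            class = "cmi_estimate")
}

#' Gaussian CMI from a covariance matrix
#'
#' Computes I(X; Y | Z) in nats from a (possibly exact) covariance matrix,
#' given index sets for the three blocks. This is the workhorse behind
#' [gaussian_cmi()] and the fast path of the greedy algorithm, where the
#' covariance of the full embedding is computed once and every candidate's
#' contribution is a sub-matrix computation.
#'
#' @param sigma Covariance matrix.
#' @param ix,iy Integer index vectors for the X and Y blocks.
#' @param iz Integer index vector for the conditioning block (may be empty).
#' @return CMI value in nats (bare numeric).
#' @export
gaussian_cmi_from_cov <- function(sigma, ix, iy, iz = integer(0)) {
  0.5 * (logdet_sub(sigma, c(ix, iz)) + logdet_sub(sigma, c(iy, iz)) -
           logdet_sub(sigma, c(ix, iy, iz)) - logdet_sub(sigma, iz))
}

# log-determinant of sigma[idx, idx] via Cholesky; empty index -> 0.
# A failed or zero-pivot Cholesky means collinear columns; name them.
logdet_sub <- function(sigma, idx) {
  if (length(idx) == 0L) return(0)
  s <- sigma[idx, idx, drop = FALSE]
  ch <- tryCatch(chol(s), error = function(e) NULL)
  if (is.null(ch) || any(diag(ch) < sqrt(.Machine$double.eps) * max(diag(ch), 1)))
    stop("singular covariance: variables {", paste(idx, collapse = ", "),
         "} are collinear or constant")
  2 * sum(log(diag(ch)))
}

#' Analytic null CDF of the Gaussian CMI estimate
#'
#' Under the null hypothesis of conditional independence, the likelihood-ratio
#' statistic 2 M I-hat is asymptotically chi-square distributed with
#' `dx * dy` degrees of freedom. This gives the probability
#' P(I-hat <= `value`) used as the analytic alternative to surrogate-based
#' null distributions for the Gaussian estimator.
#'
#' @param value CMI estimate in nats.
#' @param M Number of samples the estimate was computed from.
#' @param dims Integer vector `c(dx, dy)` with the dimensions of the two
#'   non-conditioning blocks; degrees of freedom are `prod(dims)`.
#' @return Probability in `[0, 1]`, vectorised over `value`.
#' @export
gaussian_null_cdf <- function(value, M, dims = c(1L, 1L)) {
  stopifnot(M > 0, all(dims >= 1))
  stats::pchisq(pmax(2 * M * value, 0), df = prod(dims))
}

#' Kraskov-Grassberger nearest-neighbour (conditional) mutual information
#'
#' Estimates I(X; Y | Z) in nats with the Kraskov et al. algorithm-1
#' neighbour-counting estimator (max-norm in the joint space, strict
#' inequality on the radius) and the Frenzel-Pompe digamma combination for
#' the conditional case:
#' \deqn{I = \psi(k) - \langle \psi(n_{xz}+1) + \psi(n_{yz}+1)
#'           - \psi(n_{z}+1)\rangle,}
#' reducing to \eqn{\psi(k) + \psi(M) - \langle\psi(n_x+1)+\psi(n_y+1)\rangle}
#' when Z is empty. The estimator is model-free and invariant under monotone
#' rescaling of the marginals, which makes it suitable for the strongly
#' non-Gaussian stationary distributions of chaotic map dynamics.
#'
#' Distance ties (frequent after modulo-1 maps) are broken by adding seeded
#' deterministic noise of amplitude `tie_noise` times each column's standard
#' deviation before the neighbour search.
#'
#' @inheritParams gaussian_cmi
#' @param k Number of nearest neighbours (default 4).
#' @param tie_noise Relative amplitude of the tie-breaking noise; set to 0 to
#'   disable (constant columns then raise an error).
#' @param noise_seed Seed for the tie-breaking noise, making the estimate
#'   deterministic.
#' @return Object of class `cmi_estimate` with `value` (nats), `estimator`
#'   `"ksg"`, `k` and `M`.
#' @export
ksg_cmi <- function(x, y, z = NULL, k = 4L, tie_noise = 1e-8, noise_seed = 1L) {
  x <- as.matrix(x); y <- as.matrix(y)
  z <- if (is.null(z) || length(z) == 0L) NULL else as.matrix(z)
  m <- nrow(x)
  if (nrow(y) != m || (!is.null(z) && nrow(z) != m))
    stop("x, y and z must have the same number of rows")
  if (k < 1L) stop("k must be >= 1")
  if (m <= k) stop("need more than k = ", k, " samples, got ", m)
  dat <- cbind(x, y, if (!is.null(z)) z)
  if (!all(is.finite(dat))) stop("non-finite values in input")
  sds <- apply(dat, 2, stats::sd)
  if (any(sds == 0) && tie_noise <= 0)
    stop("constant column(s) ", paste(which(sds == 0), collapse = ", "),
         " give degenerate distances; enable tie_noise")
  if (tie_noise > 0) {
    amp <- tie_noise * ifelse(sds > 0, sds, 1)
    dat <- dat + withr::with_seed(noise_seed,
      matrix(stats::rnorm(length(dat)), nrow = m) %*% diag(amp, ncol(dat)))
  }
  dx <- ncol(x); dy <- ncol(y); dz <- if (is.null(z)) 0L else ncol(z)
  value <- ksg_cmi_cpp(dat, dx, dy, dz, as.integer(k))
  structure(list(value = value, estimator = "ksg", k = as.integer(k), M = m,
                 dx = dx, dy = dy),
            class = "cmi_estimate")
}

#' @export
print.cmi_estimate <- function(x, ...) {
  cat(sprintf("CMI estimate: %.6f nats (%s estimator, M = %d%s)\n",
              x$value, x$estimator, x$M,
              if (!is.null(x$k)) paste0(", k = ", x$k) else ""))
  invisible(x)
}
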