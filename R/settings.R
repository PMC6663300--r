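#' Inference settings
#'
#' Bundles every tunable of the greedy inference: maximum lags of the
#' candidate past sets, significance level (used for the maximum, minimum
#' and omnibus tests alike), surrogate count, estimator, surrogate scheme,
#' master seed, and the FDR level applied across targets.
#'
#' The analytic chi-square null replaces the surrogate loop for the Gaussian
#' estimator by default; the nearest-neighbour estimator always uses
#' surrogates. In surrogate mode the resolution constraint `S >= 1/alpha`
#' is enforced (e.g. S = 1000 is minimal for alpha = 0.001).
#'
#' @param l_target Maximum lag of the candidate target past set.
#' @param l_sources Maximum lag of the candidate sources past set.
#' @param alpha Significance level for all hierarchical tests.
#' @param S Number of surrogates for nonparametric nulls.
#' @param estimator `"gaussian"` or `"ksg"`.
#' @param k Neighbour count for the KSG estimator.
#' @param analytic Use the analytic Gaussian null instead of surrogates;
#'   defaults to `TRUE` for the Gaussian estimator, must be `FALSE` for KSG.
#' @param surrogate_mode Passed to [surrogate_scheme()].
#' @param seed Master seed; all surrogate permutations and tie-breaking
#'   noise derive from it, making runs bit-reproducible.
#' @param q_fdr FDR level for combining omnibus p values across targets.
#' @return Object of class `inference_settings`.
#' @export
inference_settings <- function(l_target = 5L, l_sources = 5L, alpha = 0.001,
                               S = 1000L, estimator = c("gaussian", "ksg"),
                               k = 4L, analytic = NULL,
                               surrogate_mode = "auto", seed = 1L,
                               q_fdr = 0.05) {
  estimator <- match.arg(estimator)
  if (is.null(analytic)) analytic <- estimator == "gaussian"
  if (analytic && estimator != "gaussian")
    stop("the analytic null is only available for the Gaussian estimator")
  stopifnot(l_target >= 1, l_sources >= 1, alpha > 0, alpha < 1,
            k >= 1, q_fdr > 0, q_fdr <= 1)
  if (!analytic && S < 1 / alpha)
    stop("S = ", S, " surrogates cannot resolve alpha = ", alpha,
         "; need S >= 1/alpha")
  structure(list(l_target = as.integer(l_target),
                 l_sources = as.integer(l_sources),
                 alpha = alpha, S = as.integer(S), estimator = estimator,
                 k = as.integer(k), analytic = analytic,
                 surrogate_mode = surrogate_mode, seed = as.integer(seed),
                 q_fdr = q_fdr),
            class = "inference_settings")
}

#' @export
print.inference_settings <- function(x, ...) {
  cat(sprintf(paste0("inference settings: %s estimator (%s null), alpha = %g,",
                     " l_target = %d, l_sources = %d, S = %d, seed = %d,",
                     " q_fdr = %g\n"),
              x$estimator, if (x$analytic) "analytic" else "surrogate",
              x$alpha, x$l_target, x$l_sources, x$S, x$seed, x$q_fdr))
  invisible(x)
}

# Deterministic child seed below 2^31 for target-level randomness, so that
# serial and parallel (sharded) executions agree.
child_seed <- function(master, target, salt = 0L) {
  as.integer((as.double(master) * 48271 + target * 2654435 + salt * 97) %%
               2147483587) + 1L
}

# Coerce time-series input to a T x N x R array.
as_timeseries_array <- function(data) {
  if (is.matrix(data)) data <- array(data, c(nrow(data), ncol(data), 1L))
  if (!(is.array(data) && length(dim(data)) == 3L))
    stop("data must be a T x N matrix or a T x N x R array")
  if (!all(is.finite(data))) stop("non-finite values in time series")
  data
}
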