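#' Surrogate scheme for permutation testing
#'
#' Describes how the embedded realisations of a candidate variable are
#' permuted to destroy the source-target temporal relationship while leaving
#' the target, the target past and all conditioning variables untouched.
#' With several replications (trials) available, whole replications of the
#' candidate are reordered (`"shuffle_replications"`); with too few
#' replications to supply enough distinct permutations, the embedded samples
#' are shuffled within each replication (`"shuffle_embedded_samples"`).
#' `"auto"` picks replication shuffling when `R! > S`, sample shuffling
#' otherwise.
#'
#' @param mode One of `"auto"`, `"shuffle_replications"`,
#'   `"shuffle_embedded_samples"`.
#' @return Object of class `surrogate_scheme`.
#' @export
surrogate_scheme <- function(mode = c("auto", "shuffle_replications",
                                      "shuffle_embedded_samples")) {
  structure(list(mode = match.arg(mode)), class = "surrogate_scheme")
}

# Resolve "auto" given the replication count R and surrogate count S.
resolve_scheme <- function(scheme, R, S) {
  mode <- if (is.character(scheme)) scheme else scheme$mode
  if (mode == "auto")
    mode <- if (R > 1 && factorial(R) > S) "shuffle_replications"
            else "shuffle_embedded_samples"
  if (mode == "shuffle_replications" && R == 1)
    stop("shuffle_replications needs R > 1 replications; ",
         "use shuffle_embedded_samples")
  mode
}

#' Permute an embedded candidate realisation
#'
#' Returns a surrogate copy of one candidate's embedded realisation vector
#' (or jointly permuted matrix columns, as used by the omnibus test). Only
#' the candidate is permuted; callers keep the target and conditioning
#' realisations fixed, which preserves the temporal structure the null
#' hypothesis conditions on. Permutations are over whole replication blocks
#' in mode `shuffle_replications` and over embedded sample indices within
#' each replication otherwise. A surrogate may coincide with the original by
#' chance; the identity permutation is not excluded.
#'
#' @param column Numeric vector (or matrix whose rows are permuted jointly)
#'   of embedded realisations, rows pooled over replications.
#' @param replication Integer vector assigning each row to a replication
#'   (defaults to a single replication).
#' @param mode Surrogate mode, see [surrogate_scheme()]; `"auto"` resolved
#'   with `S = Inf` treated as sample shuffling when `R = 1`.
#' @param S Surrogate count used to resolve `"auto"`.
#' @return Permuted vector or matrix of the same shape.
#' @export
generate_candidate_surrogate <- function(column, replication = NULL,
                                         mode = "auto", S = 1L) {
  mat <- is.matrix(column)
  n <- if (mat) nrow(column) else length(column)
  if (is.null(replication)) replication <- rep(1L, n)
  stopifnot(length(replication) == n)
  R <- length(unique(replication))
  mode <- resolve_scheme(mode, R, S)
  idx <- seq_len(n)
  if (mode == "shuffle_replications") {
    blocks <- split(idx, replication)
    idx <- unlist(blocks[sample(length(blocks))], use.names = FALSE)
  } else {
    for (b in split(idx, replication)) idx[b] <- b[sample(length(b))]
  }
  if (mat) column[idx, , drop = FALSE] else column[idx]
}

new_te_test <- function(statistic, p_value, alpha, null_values, n, method) {
  structure(list(statistic = statistic, p_value = p_value, alpha = alpha,
                 significant = p_value < alpha, null_values = null_values,
                 n = n, method = method),
            class = "te_test")
}

#' @export
print.te_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6f nats, p = %.4g (alpha = %g) -> %s\n",
              x$method, x$statistic, x$p_value, x$alpha,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Maximum statistic test
#'
#' Step-down permutation test controlling the family-wise error rate over a
#' set of candidate contributions. The observed statistic is the maximum CMI
#' over the candidates; the null distribution is the per-surrogate maximum
#' over all candidates' surrogate CMIs, mirroring the selection process. The
#' p value is the fraction of surrogate maxima strictly larger than the
#' observed maximum (so p = 0 is attainable; configure `S > 1/alpha` for
#' adequate resolution).
#'
#' With the Gaussian estimator the surrogate loop can be skipped: treating
#' the n candidate null statistics as i.i.d., the analytic p value is
#' `1 - F(I*)^n` with `F` the chi-square null CDF ([gaussian_null_cdf()]).
#' Supply `M` (and omit `surrogate_cmis`) to use this route.
#'
#' @param cmi_values Observed CMI of each remaining candidate (nats).
#' @param alpha Significance level.
#' @param surrogate_cmis Matrix `n x S` of surrogate CMI values (candidate by
#'   surrogate), for the nonparametric route.
#' @param M Sample count, for the analytic Gaussian route.
#' @param dims Block dimensions passed to [gaussian_null_cdf()].
#' @return Object of class `te_test` with the selected index in `which_max`.
#' @export
max_statistic_test <- function(cmi_values, alpha, surrogate_cmis = NULL,
                               M = NULL, dims = c(1L, 1L)) {
  n <- length(cmi_values)
  if (n < 1L) stop("empty candidate set: stop the iteration before testing")
  stat <- max(cmi_values)
  if (!is.null(surrogate_cmis)) {
    stopifnot(nrow(surrogate_cmis) == n)
    null_max <- apply(surrogate_cmis, 2, max)
    p <- mean(null_max > stat)
    res <- new_te_test(stat, p, alpha, null_max, n, "maximum statistic (surrogate)")
  } else {
    if (is.null(M)) stop("supply surrogate_cmis or M for the analytic null")
    p <- 1 - gaussian_null_cdf(stat, M, dims)^n
    res <- new_te_test(stat, p, alpha, NULL, n, "maximum statistic (analytic)")
  }
  res$which_max <- which.max(cmi_values)
  res
}

#' Minimum statistic test
#'
#' Used by the pruning step: tests whether the weakest selected variable
#' still carries a significant contribution, controlling the family-wise
#' error rate across the selected set. It works like the maximum statistic
#' test with the minimum in place of the maximum: the observed statistic is
#' the minimum CMI over the selected variables, the null distribution is the
#' per-surrogate minimum, and the p value is the fraction of surrogate
#' minima strictly larger than the observed minimum. A non-significant
#' result means the weakest variable is indistinguishable from the null and
#' is removed. Analytic route: `p = (1 - F(I_min))^n`.
#'
#' @inheritParams max_statistic_test
#' @return Object of class `te_test` with the weakest index in `which_min`.
#' @export
min_statistic_test <- function(cmi_values, alpha, surrogate_cmis = NULL,
                               M = NULL, dims = c(1L, 1L)) {
  n <- length(cmi_values)
  if (n < 1L) stop("empty selected set: nothing to prune")
  stat <- min(cmi_values)
  if (!is.null(surrogate_cmis)) {
    stopifnot(nrow(surrogate_cmis) == n)
    null_min <- apply(surrogate_cmis, 2, min)
    p <- mean(null_min > stat)
    res <- new_te_test(stat, p, alpha, null_min, n, "minimum statistic (surrogate)")
  } else {
    if (is.null(M)) stop("supply surrogate_cmis or M for the analytic null")
    p <- (1 - gaussian_null_cdf(stat, M, dims))^n
    res <- new_te_test(stat, p, alpha, NULL, n, "minimum statistic (analytic)")
  }
  res$which_min <- which.min(cmi_values)
  res
}

#' Omnibus test of the collective transfer entropy
#'
#' Tests the collective transfer entropy T* = I(X_sel; Y_t | Y_past) from
#' the whole selected source set against the null hypothesis of zero
#' transfer. The null distribution is built by jointly permuting the rows of
#' all selected source realisations (a single test, no extreme statistic);
#' the p value is the fraction of surrogate statistics strictly larger than
#' T*. Analytic route: chi-square with `df` degrees of freedom (the number
#' of selected source variables for scalar candidates).
#'
#' @param te_value Observed collective transfer entropy (nats).
#' @param alpha Significance level.
#' @param null_values Vector of surrogate statistics, for the nonparametric
#'   route.
#' @param M Sample count, for the analytic route.
#' @param df Degrees of freedom for the analytic route.
#' @return Object of class `te_test`.
#' @export
omnibus_test <- function(te_value, alpha, null_values = NULL, M = NULL, df = 1L) {
  if (!is.null(null_values)) {
    p <- mean(null_values > te_value)
    new_te_test(te_value, p, alpha, null_values, 1L, "omnibus (surrogate)")
  } else {
    if (is.null(M)) stop("supply null_values or M for the analytic null")
    p <- 1 - stats::pchisq(pmax(2 * M * te_value, 0), df = df)
    new_te_test(te_value, p, alpha, NULL, 1L, "omnibus (analytic)")
  }
}

#' Per-variable false positive rate implied by the maximum statistic test
#'
#' The maximum statistic correction at level `alpha_max` over `n`
#' comparisons is equivalent to the Dunn-Sidak correction: the false
#' positive rate for a single variable is
#' \deqn{v_{FPR} = 1 - (1 - \alpha_{max})^{1/n},}
#' which is bounded below by the Bonferroni rate `alpha_max / n`.
#'
#' @param alpha_max Significance level of the maximum statistic test.
#' @param n Number of comparisons (candidates).
#' @return Single-variable false positive rate.
#' @export
vfpr_from_alpha <- function(alpha_max, n) {
  stopifnot(alpha_max > 0, alpha_max < 1, n >= 1)
  1 - (1 - alpha_max)^(1 / n)
}

#' Per-target false positive rate across greedy iterations
#'
#' Accounts for all iterations of the step-down selection: the probability
#' that at least one selected source is a false positive after up to `n`
#' greedy steps at level `alpha_max` is the geometric sum
#' \deqn{t_{FPR} = \sum_{j=1}^{n} \alpha_{max}^j
#'   = \alpha_{max}\frac{1-\alpha_{max}^n}{1-\alpha_{max}},}
#' which is approximately `alpha_max` for the small levels used in practice,
#' even for large `n`.
#'
#' @inheritParams vfpr_from_alpha
#' @param n Number of greedy steps.
#' @return Per-target (family-wise) false positive rate.
#' @export
tfpr_from_alpha <- function(alpha_max, n) {
  stopifnot(alpha_max > 0, alpha_max < 1, n >= 1)
  alpha_max * (1 - alpha_max^n) / (1 - alpha_max)
}

#' Combine omnibus p values across targets by FDR
#'
#' Benjamini-Hochberg step-up procedure at level `q` over the omnibus
#' p values of the targets with a non-empty selected source set. Targets
#' that are rejected lose all their inferred links in the assembled network.
#'
#' @param p_values Numeric vector of omnibus p values.
#' @param q FDR level.
#' @return Logical vector: `TRUE` where the target's links are kept.
#' @export
fdr_combine_targets <- function(p_values, q = 0.05) {
  if (length(p_values) == 0L) return(logical(0))
  stopifnot(all(p_values >= 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "BH") <= q
}
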