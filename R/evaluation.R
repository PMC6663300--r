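# Scoring inferred networks against ground truth as a binary classification
# over ordered off-diagonal node pairs, plus the coupling-lag error and the
# empty-network false-positive-rate protocol.

as_adjacency <- function(x) {
  if (inherits(x, "te_network_result")) return(inferred_adjacency(x))
  if (inherits(x, "ground_truth_network")) return(x$adjacency)
  if (is.matrix(x)) return(x > 0)
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as an adjacency")
}

#' Confusion counts for directed link classification
#'
#' Compares an inferred network with the ground truth over all ordered
#' off-diagonal node pairs (self-pairs are excluded: self-dynamics are not
#' links), ignoring lags. Counts satisfy
#' `TP + FP + TN + FN = N (N - 1)`.
#'
#' @param inferred Inference result, `ground_truth_network`, or adjacency
#'   matrix (`[source, target]`).
#' @param truth Ground truth in any of the same forms.
#' @return List of class `confusion_counts` with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(inferred, truth) {
  a <- as_adjacency(inferred); b <- as_adjacency(truth)
  if (!all(dim(a) == dim(b))) stop("node count mismatch between networks")
  off <- !diag(nrow(a))
  structure(list(TP = sum(a & b & off), FP = sum(a & !b & off),
                 TN = sum(!a & !b & off), FN = sum(!a & b & off)),
            class = "confusion_counts")
}

#' Precision, recall and specificity
#'
#' Standard binary-classification ratios: precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)`. A ratio with a zero denominator
#' is undefined and reported as `NA` (and should be excluded from
#' cross-run averages) rather than coerced to 0 or 1.
#'
#' @param counts A `confusion_counts` object (or list with TP/FP/TN/FN).
#' @return Named list with `precision`, `recall`, `specificity`.
#' @export
classification_scores <- function(counts) {
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  list(precision = ratio(counts$TP, counts$TP + counts$FP),
       recall = ratio(counts$TP, counts$TP + counts$FN),
       specificity = ratio(counts$TN, counts$TN + counts$FP))
}

#' Relative coupling-lag error
#'
#' Mean absolute error between the true and the inferred coupling lags over
#' the correctly recalled links (one representative inferred lag per link:
#' the lag of the selected variable with the largest final conditional
#' contribution), divided by the error expected at random, i.e. the mean
#' absolute difference of two i.i.d. uniform integers on the lag range
#' (1.6 for lags 1..5). Links where the true lag is merely among the
#' selected lags are additionally counted in `multi_lag_hits`.
#'
#' @param result A `te_network_result`.
#' @param truth A `ground_truth_network`.
#' @param lag_range Admissible lag range used for the random-expectation
#'   normaliser (defaults to the truth's).
#' @return List with `relative_error` (`NA` when there are no true
#'   positives), `n_tp`, `normalizer`, and `multi_lag_hits`.
#' @export
relative_lag_error <- function(result, truth, lag_range = NULL) {
  if (is.null(lag_range)) lag_range <- truth$lag_range
  normalizer <- mean(abs(outer(lag_range, lag_range, "-")))
  links <- result$links
  if (nrow(links) == 0)
    return(list(relative_error = NA_real_, n_tp = 0L,
                normalizer = normalizer, multi_lag_hits = 0L))
  tp <- truth$adjacency[cbind(links$source, links$target)]
  links <- links[tp, , drop = FALSE]
  if (nrow(links) == 0)
    return(list(relative_error = NA_real_, n_tp = 0L,
                normalizer = normalizer, multi_lag_hits = 0L))
  true_lag <- truth$lags[cbind(links$source, links$target)]
  err <- mean(abs(true_lag - links$lag))
  hits <- sum(mapply(function(ls, tl) {
    tl %in% as.integer(strsplit(ls, "|", fixed = TRUE)[[1]])
  }, links$lags, true_lag))
  list(relative_error = err / normalizer, n_tp = nrow(links),
       normalizer = normalizer, multi_lag_hits = as.integer(hits))
}

#' Percentile band of the expected empty-network false positive rate
#'
#' Under the complete null, the number of targets with at least one inferred
#' source in a network of N targets is approximately Binomial(N, alpha);
#' the experiment reports the average of `n_repeats` such rates. This
#' computes percentiles of the distribution of that average,
#' `mean(Binomial(N, alpha)/N)`, by Monte Carlo.
#'
#' @param N Number of targets.
#' @param alpha Per-target false positive rate.
#' @param n_repeats Number of simulation repeats being averaged.
#' @param probs Percentiles to report.
#' @param n_draws Monte Carlo sample size.
#' @param seed Seed for the Monte Carlo draw.
#' @return Named numeric vector of percentiles.
#' @export
binomial_fpr_band <- function(N, alpha, n_repeats, probs = c(0.05, 0.95),
                              n_draws = 100000L, seed = 1L) {
  withr::with_seed(seed, {
    draws <- matrix(stats::rbinom(n_draws * n_repeats, N, alpha) / N,
                    nrow = n_draws)
    stats::quantile(rowMeans(draws), probs = probs)
  })
}

#' Empty-network false positive rate experiment
#'
#' Validation protocol for the per-target family-wise error rate: simulate
#' autoregressive dynamics on empty networks (no links, self-coupling only),
#' run the full inference, and count the fraction of targets with at least
#' one inferred source (before network-level FDR, which would mask the rate
#' being validated). Every inferred link is a false positive by
#' construction. The empirical mean rate per (N, alpha) cell is compared
#' with the 5th-95th percentile band of the averaged binomial rate.
#'
#' @param N_list Network sizes.
#' @param T Samples per simulation.
#' @param alpha_list Significance levels.
#' @param n_repeats Simulation repeats per cell.
#' @param settings Baseline [inference_settings()]; `alpha` is overridden
#'   per cell.
#' @param seed Master seed for the simulations.
#' @param beta Self-coupling of the null dynamics.
#' @return Data frame: N, alpha, fpr (mean rate), band_lo, band_hi, inside.
#' @export
empty_network_fpr_experiment <- function(N_list, T, alpha_list,
                                         n_repeats = 50L,
                                         settings = inference_settings(),
                                         seed = 1L, beta = 0.5) {
  cells <- expand.grid(N = N_list, alpha = alpha_list)
  out <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    N <- cells$N[ci]; alpha <- cells$alpha[ci]
    s <- settings
    s$alpha <- alpha
    if (!s$analytic && s$S < 1 / alpha)
      stop("S = ", s$S, " cannot resolve alpha = ", alpha)
    net <- empty_network(N, beta = beta)
    rates <- vapply(seq_len(n_repeats), function(rep) {
      dat <- simulate_var(net, T, seed = child_seed(seed, rep, ci))
      res <- infer_network(dat, s)
      with_src <- vapply(res$targets,
                         function(r) !is.null(r$selected_sources_past) &&
                           nrow(r$selected_sources_past) > 0, logical(1))
      mean(with_src)
    }, numeric(1))
    band <- binomial_fpr_band(N, alpha, n_repeats,
                              seed = child_seed(seed, ci, 999L))
    out[[ci]] <- data.frame(N = N, alpha = alpha, fpr = mean(rates),
                            band_lo = band[1], band_hi = band[2],
                            inside = mean(rates) >= band[1] &
                              mean(rates) <= band[2])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
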