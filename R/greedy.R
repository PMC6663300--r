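# Greedy per-target inference: nonuniform embedding of the target past
# (step 1), of the sources past (step 2), pruning (step 3) and the omnibus
# test (step 4), plus network assembly across targets.

# Build the pooled embedding shared by all targets of one dataset: lagged
# copies of every process at lags 1..L and the present (lag-0) columns. The
# first L = max(l_target, l_sources) samples of each replication are dropped
# once, so every iteration of every step sees the same realisation rows.
build_engine <- function(data, settings) {
  data <- as_timeseries_array(data)
  T <- dim(data)[1]; N <- dim(data)[2]; R <- dim(data)[3]
  L <- max(settings$l_target, settings$l_sources)
  if (T <= L + 10) stop("need T > max lag + 10 samples, got T = ", T)
  rows_per_rep <- T - L
  M <- rows_per_rep * R
  map <- data.frame(process = rep(seq_len(N), each = L),
                    lag = rep(seq_len(L), times = N))
  lagged <- matrix(NA_real_, M, N * L)
  present <- matrix(NA_real_, M, N)
  replication <- rep(seq_len(R), each = rows_per_rep)
  t_idx <- (L + 1):T
  for (r in seq_len(R)) {
    rows <- (r - 1) * rows_per_rep + seq_len(rows_per_rep)
    present[rows, ] <- data[t_idx, , r]
    for (col in seq_len(N * L))
      lagged[rows, col] <- data[t_idx - map$lag[col], map$process[col], r]
  }
  eng <- list(N = N, T = T, R = R, L = L, M = M, map = map, lagged = lagged,
              present = present, replication = replication,
              settings = settings)
  if (settings$estimator == "gaussian") {
    all_cols <- cbind(lagged, present)
    eng$sigma <- crossprod(scale(all_cols, center = TRUE, scale = FALSE)) / M
  }
  eng
}

# Observed CMI of lagged columns `ix` (candidate/selected) with the present
# of `target`, given lagged columns `iz`.
engine_cmi <- function(eng, target, ix, iz) {
  s <- eng$settings
  if (s$estimator == "gaussian") {
    nl <- ncol(eng$lagged)
    gaussian_cmi_from_cov(eng$sigma, ix, nl + target, iz)
  } else {
    ksg_cmi(eng$lagged[, ix, drop = FALSE], eng$present[, target],
            if (length(iz)) eng$lagged[, iz, drop = FALSE],
            k = s$k, noise_seed = child_seed(s$seed, target, 1L))$value
  }
}

# CMI of an explicit (permuted) realisation matrix against the target
# present, given lagged columns `iz`; used for surrogate statistics.
engine_cmi_raw <- function(eng, target, xmat, iz) {
  s <- eng$settings
  z <- if (length(iz)) eng$lagged[, iz, drop = FALSE]
  if (s$estimator == "gaussian") {
    gaussian_cmi(xmat, eng$present[, target], z)$value
  } else {
    ksg_cmi(xmat, eng$present[, target], z, k = s$k,
            noise_seed = child_seed(s$seed, target, 2L))$value
  }
}

# n x S matrix of surrogate CMI values: each remaining candidate is permuted
# independently, with the same conditioning set as the observed statistic of
# the current iteration.
surrogate_cmi_matrix <- function(eng, target, cand_cols, iz_of = NULL, iz = NULL) {
  s <- eng$settings
  mode <- resolve_scheme(s$surrogate_mode, eng$R, s$S)
  n <- length(cand_cols)
  out <- matrix(NA_real_, n, s$S)
  for (j in seq_len(n)) {
    col <- eng$lagged[, cand_cols[j]]
    izj <- if (is.null(iz_of)) iz else iz_of[[j]]
    for (srg in seq_len(s$S)) {
      perm <- generate_candidate_surrogate(col, eng$replication, mode, s$S)
      out[j, srg] <- engine_cmi_raw(eng, target, perm, izj)
    }
  }
  out
}

# One greedy selection stage (used for both the target past and the sources
# past): repeatedly estimate every remaining candidate's conditional
# contribution, pick the maximum, test it with the maximum statistic, and
# move it into the selected set while significant. Ties in the argmax break
# to the lowest process index, then the smallest lag.
greedy_select <- function(eng, target, cand_cols, fixed_iz, settings, seed_salt) {
  selected <- integer(0)
  log <- list()
  iter <- 0L
  while (length(cand_cols) > 0L) {
    iter <- iter + 1L
    iz <- c(fixed_iz, selected)
    obs <- vapply(cand_cols, function(cc) engine_cmi(eng, target, cc, iz),
                  numeric(1))
    ord <- order(-obs, eng$map$process[cand_cols], eng$map$lag[cand_cols])
    best <- ord[1]
    if (settings$analytic) {
      test <- max_statistic_test(obs, settings$alpha, M = eng$M)
    } else {
      surr <- withr::with_seed(
        child_seed(settings$seed, target, seed_salt + iter),
        surrogate_cmi_matrix(eng, target, cand_cols, iz = iz))
      test <- max_statistic_test(obs, settings$alpha, surrogate_cmis = surr)
    }
    log[[iter]] <- data.frame(iteration = iter,
                              process = eng$map$process[cand_cols[best]],
                              lag = eng$map$lag[cand_cols[best]],
                              cmi = obs[best], p_value = test$p_value,
                              significant = test$significant)
    if (!test$significant) break
    selected <- c(selected, cand_cols[best])
    cand_cols <- cand_cols[-best]
  }
  list(selected = selected,
       trace = if (length(log)) do.call(rbind, log) else NULL)
}

# Pruning stage: while the weakest selected source variable fails the
# minimum statistic test, remove it; stop at the first significant minimum.
# Ties in the argmin break to the lowest process index, then smallest lag.
greedy_prune <- function(eng, target, sel_cols, fixed_iz, settings) {
  removed <- integer(0)
  final_cmi <- NULL
  iter <- 0L
  while (length(sel_cols) > 0L) {
    iter <- iter + 1L
    obs <- vapply(seq_along(sel_cols), function(j) {
      engine_cmi(eng, target, sel_cols[j], c(fixed_iz, sel_cols[-j]))
    }, numeric(1))
    ord <- order(obs, eng$map$process[sel_cols], eng$map$lag[sel_cols])
    worst <- ord[1]
    if (settings$analytic) {
      test <- min_statistic_test(obs, settings$alpha, M = eng$M)
    } else {
      iz_of <- lapply(seq_along(sel_cols),
                      function(j) c(fixed_iz, sel_cols[-j]))
      surr <- withr::with_seed(
        child_seed(settings$seed, target, 7000L + iter),
        surrogate_cmi_matrix(eng, target, sel_cols, iz_of = iz_of))
      test <- min_statistic_test(obs, settings$alpha, surrogate_cmis = surr)
    }
    if (test$significant) { final_cmi <- obs; break }
    removed <- c(removed, sel_cols[worst])
    sel_cols <- sel_cols[-worst]
  }
  list(selected = sel_cols, removed = removed, final_cmi = final_cmi)
}

cols_to_vars <- function(eng, cols, extra = NULL) {
  d <- data.frame(process = eng$map$process[cols], lag = eng$map$lag[cols])
  if (!is.null(extra)) d <- cbind(d, extra)
  d
}

#' Step 1: select the target's own past variables
#'
#' Greedy optimisation of the active information storage: iteratively adds
#' the candidate past variable of the target that maximally reduces the
#' uncertainty about its present state, as long as the maximum statistic
#' test deems the contribution significant. The resulting nonuniform
#' self-embedding is the conditioning context for all source selection.
#'
#' @param data `T x N` matrix or `T x N x R` array of observations.
#' @param target Target process index (1-based).
#' @param settings An [inference_settings()] object.
#' @return List with `selected` (data frame of process/lag) and `trace`
#'   (per-iteration chosen variable, statistic and p value).
#' @export
select_target_past <- function(data, target, settings = inference_settings()) {
  eng <- build_engine(data, settings)
  res <- target_past_stage(eng, target, settings)
  list(selected = cols_to_vars(eng, res$selected), trace = res$trace)
}

target_past_stage <- function(eng, target, settings) {
  cand <- which(eng$map$process == target & eng$map$lag <= settings$l_target)
  greedy_select(eng, target, cand, integer(0), settings, seed_salt = 1000L)
}

source_past_stage <- function(eng, target, target_past_cols, settings) {
  cand <- which(eng$map$process != target & eng$map$lag <= settings$l_sources)
  greedy_select(eng, target, cand, target_past_cols, settings,
                seed_salt = 3000L)
}

#' Step 2: select source past variables
#'
#' Greedy selection over all lagged candidate variables of the other
#' processes, conditioning each contribution on the selected target past and
#' the sources selected so far (the first accepted variable therefore
#' carries plain bivariate transfer entropy). Conditioning prevents
#' candidates with only redundant information (common drivers, pathway
#' effects) from entering, while allowing synergistic combinations.
#'
#' @inheritParams select_target_past
#' @param target_past Data frame of previously selected target-past
#'   variables (columns `process`, `lag`), e.g. from [select_target_past()].
#' @return List with `selected` and `trace` as in [select_target_past()].
#' @export
select_source_past <- function(data, target, target_past,
                               settings = inference_settings()) {
  eng <- build_engine(data, settings)
  tp_cols <- vars_to_cols(eng, target_past)
  res <- source_past_stage(eng, target, tp_cols, settings)
  list(selected = cols_to_vars(eng, res$selected), trace = res$trace)
}

vars_to_cols <- function(eng, vars) {
  if (is.null(vars) || nrow(vars) == 0L) return(integer(0))
  vapply(seq_len(nrow(vars)), function(i) {
    which(eng$map$process == vars$process[i] & eng$map$lag == vars$lag[i])
  }, integer(1))
}

#' Step 3: prune the selected source variables
#'
#' Re-examines every selected source variable in the context of the final
#' selected set: the variable with the minimal conditional contribution is
#' tested with the minimum statistic and removed while non-significant, so
#' that variables accepted early that have become redundant are discarded.
#'
#' @inheritParams select_source_past
#' @param sources Data frame of selected source variables (`process`, `lag`).
#' @return List with `selected`, `removed` (both data frames) and
#'   `final_cmi` (conditional contribution of each retained variable).
#' @export
prune_sources <- function(data, target, target_past, sources,
                          settings = inference_settings()) {
  eng <- build_engine(data, settings)
  tp_cols <- vars_to_cols(eng, target_past)
  src_cols <- vars_to_cols(eng, sources)
  res <- greedy_prune(eng, target, src_cols, tp_cols, settings)
  list(selected = cols_to_vars(eng, res$selected,
                               if (length(res$selected))
                                 data.frame(final_cmi = res$final_cmi)),
       removed = cols_to_vars(eng, res$removed),
       final_cmi = res$final_cmi)
}

# Full four-step pipeline for one target on a prepared engine.
infer_target_engine <- function(eng, target, settings) {
  st1 <- target_past_stage(eng, target, settings)
  st2 <- source_past_stage(eng, target, st1$selected, settings)
  st3 <- greedy_prune(eng, target, st2$selected, st1$selected, settings)
  sel <- st3$selected
  omnibus_te <- NA_real_
  omnibus_p <- NA_real_
  rejected <- FALSE
  if (length(sel) > 0L) {
    omnibus_te <- engine_cmi(eng, target, sel, st1$selected)
    if (settings$analytic) {
      ot <- omnibus_test(omnibus_te, settings$alpha, M = eng$M,
                         df = length(sel))
    } else {
      mode <- resolve_scheme(settings$surrogate_mode, eng$R, settings$S)
      null_vals <- withr::with_seed(
        child_seed(settings$seed, target, 9000L),
        vapply(seq_len(settings$S), function(s) {
          perm <- generate_candidate_surrogate(
            eng$lagged[, sel, drop = FALSE], eng$replication, mode, settings$S)
          engine_cmi_raw(eng, target, perm, st1$selected)
        }, numeric(1)))
      ot <- omnibus_test(omnibus_te, settings$alpha, null_values = null_vals)
    }
    omnibus_p <- ot$p_value
    if (!ot$significant) { rejected <- TRUE; sel <- integer(0) }
  }
  sources <- cols_to_vars(eng, sel,
                          if (length(sel))
                            data.frame(final_cmi = st3$final_cmi))
  structure(list(
    target = target,
    selected_target_past = cols_to_vars(eng, st1$selected),
    selected_sources_past = sources,
    removed_in_pruning = cols_to_vars(eng, st3$removed),
    rejected_by_omnibus = rejected,
    omnibus_te = omnibus_te, omnibus_p = omnibus_p,
    M = eng$M,
    trace = list(target_past = st1$trace, sources = st2$trace)),
    class = "target_inference")
}

#' Infer the information contributors of a single target
#'
#' Runs the four inference steps in order: target-past selection, source
#' selection, pruning, and the omnibus test on the collective transfer
#' entropy of the final selected source set. The selected source set is only
#' accepted if every test is passed: when the omnibus test fails, the result
#' carries an empty source set (with the omnibus p value retained). Results
#' are bit-reproducible given the settings' master seed.
#'
#' @inheritParams select_target_past
#' @return Object of class `target_inference`.
#' @export
infer_target <- function(data, target, settings = inference_settings()) {
  eng <- build_engine(data, settings)
  infer_target_engine(eng, target, settings)
}

#' @export
print.target_inference <- function(x, ...) {
  ns <- nrow(x$selected_sources_past)
  cat(sprintf("target %d: %d target-past, %d source variables%s\n",
              x$target, nrow(x$selected_target_past), ns,
              if (!is.na(x$omnibus_p))
                sprintf(" (omnibus TE = %.4f nats, p = %.4g)",
                        x$omnibus_te, x$omnibus_p) else ""))
  invisible(x)
}

#' Infer the directed network over all targets
#'
#' Runs [infer_target()] independently for every requested target (serially
#' or on a fork cluster: results are identical either way because each
#' target only uses its own derived seed), applies Benjamini-Hochberg FDR
#' correction across the omnibus p values, and assembles the directed links.
#' A link X -> Y exists whenever the (FDR-surviving) selected source set of
#' target Y contains any past variable of process X; all selected lags are
#' reported, with the lag of the variable carrying the largest final
#' conditional contribution as the representative coupling lag.
#'
#' @inheritParams select_target_past
#' @param targets Integer vector of targets to analyse (default: all).
#' @param workers Number of parallel workers (forked via
#'   `parallel::mclapply`; 1 = serial).
#' @return Object of class `te_network_result` with elements `links` (data
#'   frame: source, target, lags, lag, te, omnibus_p), `targets` (per-target
#'   results), `fdr` (per-target keep/reject) and `N`.
#' @export
infer_network <- function(data, settings = inference_settings(),
                          targets = NULL, workers = 1L) {
  data <- as_timeseries_array(data)
  N <- dim(data)[2]
  if (N < 2) stop("need at least 2 processes")
  if (is.null(targets)) targets <- seq_len(N)
  eng <- build_engine(data, settings)
  run_one <- function(tg) {
    tryCatch(infer_target_engine(eng, tg, settings),
             error = function(e) structure(list(target = tg,
                                                error = conditionMessage(e)),
                                           class = "target_inference_error"))
  }
  results <- if (workers > 1L) {
    parallel::mclapply(targets, run_one, mc.cores = workers)
  } else {
    lapply(targets, run_one)
  }
  names(results) <- as.character(targets)
  failed <- vapply(results, inherits, logical(1), "target_inference_error")
  ok <- results[!failed]
  has_sources <- vapply(ok, function(r) nrow(r$selected_sources_past) > 0,
                        logical(1))
  fdr <- data.frame(target = vapply(ok, `[[`, integer(1), "target"),
                    omnibus_p = vapply(ok, `[[`, numeric(1), "omnibus_p"),
                    keep = FALSE)
  if (any(has_sources)) {
    fdr$keep[has_sources] <-
      fdr_combine_targets(fdr$omnibus_p[has_sources], settings$q_fdr)
  }
  links <- assemble_links(ok, fdr)
  structure(list(N = N, links = links, targets = results, fdr = fdr,
                 settings = settings,
                 failures = results[failed]),
            class = "te_network_result")
}

assemble_links <- function(results, fdr) {
  rows <- list()
  for (r in results) {
    if (nrow(r$selected_sources_past) == 0) next
    if (!fdr$keep[fdr$target == r$target]) next
    for (p in unique(r$selected_sources_past$process)) {
      vars <- r$selected_sources_past[r$selected_sources_past$process == p, ]
      rows[[length(rows) + 1L]] <- data.frame(
        source = p, target = r$target,
        lags = paste(sort(vars$lag), collapse = "|"),
        lag = vars$lag[which.max(vars$final_cmi)],
        te = r$omnibus_te, omnibus_p = r$omnibus_p)
    }
  }
  if (length(rows) == 0)
    return(data.frame(source = integer(0), target = integer(0),
                      lags = character(0), lag = integer(0),
                      te = numeric(0), omnibus_p = numeric(0)))
  out <- do.call(rbind, rows)
  out[order(out$source, out$target), , drop = FALSE]
}

#' @export
print.te_network_result <- function(x, ...) {
  cat(sprintf("inferred network: %d nodes, %d directed links (q_fdr = %g)\n",
              x$N, nrow(x$links), x$settings$q_fdr))
  invisible(x)
}

#' Adjacency matrix of an inference result
#'
#' @param result A `te_network_result`.
#' @return `N x N` logical matrix, `[source, target]` orientation.
#' @export
inferred_adjacency <- function(result) {
  adj <- matrix(FALSE, result$N, result$N)
  if (nrow(result$links) > 0)
    adj[cbind(result$links$source, result$links$target)] <- TRUE
  adj
}
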