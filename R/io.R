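# Readers and writers: comma-delimited time series (one file per
# replication, rows = time, header = process labels), JSON networks and
# ground truths, CSV score tables, and the replication-suite orchestrator.

NETWORK_SCHEMA_VERSION <- 1L

#' Write a multivariate time series to delimited text
#'
#' One CSV per replication: header row of process labels, rows are time
#' samples. For a single replication `path` is used as-is; for R > 1 the
#' files are named `<stem>_rep<r>.csv`.
#'
#' @param data `T x N` matrix or `T x N x R` array.
#' @param path Output file (or stem when R > 1).
#' @return Invisibly, the vector of files written.
#' @export
write_timeseries <- function(data, path) {
  data <- as_timeseries_array(data)
  N <- dim(data)[2]; R <- dim(data)[3]
  labels <- if (!is.null(dimnames(data)[[2]])) dimnames(data)[[2]]
            else paste0("P", seq_len(N))
  files <- if (R == 1) path else
    file.path(dirname(path),
              sprintf("%s_rep%d.csv",
                      sub("\\.csv$", "", basename(path)), seq_len(R)))
  for (r in seq_len(R)) {
    m <- data[, , r, drop = FALSE]; dim(m) <- dim(data)[1:2]
    colnames(m) <- labels
    utils::write.csv(m, files[r], row.names = FALSE)
  }
  invisible(files)
}

#' Read a multivariate time series from delimited text
#'
#' Reads one or more CSV files (one per replication) written in the layout
#' of [write_timeseries()] and pools them into a `T x N x R` array. All
#' replications must agree in shape; ragged rows and non-numeric cells are
#' rejected with the offending position named.
#'
#' @param paths Character vector of files, one per replication.
#' @return `T x N x R` numeric array with process labels as column names.
#' @export
read_timeseries <- function(paths) {
  stopifnot(length(paths) >= 1, all(file.exists(paths)))
  mats <- lapply(paths, function(p) {
    df <- utils::read.csv(p, check.names = FALSE, colClasses = "character")
    m <- suppressWarnings(vapply(df, as.numeric, numeric(nrow(df))))
    if (nrow(df) == 1L) m <- matrix(m, nrow = 1, dimnames = list(NULL, names(df)))
    bad <- which(is.na(m) & !is.na(as.matrix(df)), arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("non-numeric cell in %s at row %d, column '%s'",
                   p, bad[1, 1], colnames(m)[bad[1, 2]]))
    if (anyNA(m))
      stop(sprintf("missing value in %s at row %d", p,
                   which(is.na(m), arr.ind = TRUE)[1, 1]))
    m
  })
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("replication files disagree in shape: ",
         paste(sprintf("%s is %dx%d", basename(paths), dims[1, ], dims[2, ]),
               collapse = ", "))
  out <- array(NA_real_, c(dims[1, 1], dims[2, 1], length(mats)))
  for (r in seq_along(mats)) out[, , r] <- mats[[r]]
  dimnames(out) <- list(NULL, colnames(mats[[1]]), NULL)
  out
}

#' Write a ground-truth network as a JSON edge list
#'
#' @param net A `ground_truth_network`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_ground_truth <- function(net, path) {
  idx <- which(net$adjacency, arr.ind = TRUE)
  edges <- data.frame(source = as.integer(idx[, 1]),
                      target = as.integer(idx[, 2]))
  edges$lag <- net$lags[idx]
  edges$weight <- net$weights[idx]
  obj <- list(schema_version = NETWORK_SCHEMA_VERSION,
              kind = "ground_truth",
              N = net$N, beta = net$beta, lag_range = net$lag_range,
              edges = edges[order(edges$source, edges$target), , drop = FALSE])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read a ground-truth network from JSON
#'
#' @param path File written by [write_ground_truth()].
#' @return A `ground_truth_network`.
#' @export
read_ground_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  check_schema(obj, "ground_truth", path)
  N <- obj$N
  adj <- matrix(FALSE, N, N); lags <- matrix(0L, N, N)
  weights <- matrix(0, N, N)
  e <- obj$edges
  if (length(e) && length(e$source)) {
    adj[cbind(e$source, e$target)] <- TRUE
    lags[cbind(e$source, e$target)] <- as.integer(e$lag)
    weights[cbind(e$source, e$target)] <- e$weight
  }
  structure(list(N = N, adjacency = adj, lags = lags, weights = weights,
                 beta = obj$beta, lag_range = as.integer(obj$lag_range)),
            class = "ground_truth_network")
}

check_schema <- function(obj, kind, path) {
  if (is.null(obj$schema_version) ||
      obj$schema_version != NETWORK_SCHEMA_VERSION)
    stop(path, ": unsupported schema version ",
         if (is.null(obj$schema_version)) "<missing>" else obj$schema_version,
         " (expected ", NETWORK_SCHEMA_VERSION, ")")
  if (!identical(obj$kind, kind))
    stop(path, ": expected a '", kind, "' file, found '", obj$kind, "'")
}

#' Write an inference result to JSON (and optionally a CSV edge list)
#'
#' The JSON carries the schema version, a full echo of the settings, the
#' per-target records (selected variables with their statistics, omnibus
#' results, FDR flags) and the link table. Field ordering is deterministic,
#' so identical results serialise to identical files.
#'
#' @param result A `te_network_result`.
#' @param path JSON output file.
#' @param csv_path Optional path for a flat CSV edge list
#'   (source, target, lag, te, p).
#' @return Invisibly, `path`.
#' @export
write_network <- function(result, path, csv_path = NULL) {
  tg <- lapply(result$targets, function(r) {
    if (inherits(r, "target_inference_error"))
      return(list(target = r$target, error = r$error))
    list(target = r$target,
         selected_target_past = r$selected_target_past,
         selected_sources_past = r$selected_sources_past,
         removed_in_pruning = r$removed_in_pruning,
         rejected_by_omnibus = r$rejected_by_omnibus,
         omnibus_te = r$omnibus_te, omnibus_p = r$omnibus_p, M = r$M)
  })
  obj <- list(schema_version = NETWORK_SCHEMA_VERSION,
              kind = "inference_result",
              N = result$N,
              settings = unclass(result$settings),
              links = result$links,
              fdr = result$fdr,
              targets = tg)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  if (!is.null(csv_path)) {
    edge <- result$links[, c("source", "target", "lag", "te", "omnibus_p")]
    names(edge)[5] <- "p"
    utils::write.csv(edge, csv_path, row.names = FALSE)
  }
  invisible(path)
}

#' Read an inference result from JSON
#'
#' Restores the link table, per-target records and settings written by
#' [write_network()].
#'
#' @param path JSON file.
#' @return Object of class `te_network_result`.
#' @export
read_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  check_schema(obj, "inference_result", path)
  links <- as.data.frame(obj$links)
  if (nrow(links) == 0)
    links <- data.frame(source = integer(0), target = integer(0),
                        lags = character(0), lag = integer(0),
                        te = numeric(0), omnibus_p = numeric(0))
  targets <- lapply(obj$targets, function(r) {
    if (!is.null(r$error))
      return(structure(list(target = r$target, error = r$error),
                       class = "target_inference_error"))
    r$selected_target_past <- as.data.frame(r$selected_target_past)
    r$selected_sources_past <- as.data.frame(r$selected_sources_past)
    r$removed_in_pruning <- as.data.frame(r$removed_in_pruning)
    r$omnibus_te <- if (is.null(r$omnibus_te)) NA_real_ else r$omnibus_te
    r$omnibus_p <- if (is.null(r$omnibus_p)) NA_real_ else r$omnibus_p
    structure(r, class = "target_inference")
  })
  names(targets) <- vapply(targets, function(r) as.character(r$target),
                           character(1))
  settings <- obj$settings
  class(settings) <- "inference_settings"
  structure(list(N = obj$N, links = links, targets = targets,
                 fdr = as.data.frame(obj$fdr), settings = settings,
                 failures = list()),
            class = "te_network_result")
}

#' Run a generate-infer-evaluate replication suite
#'
#' Orchestrates the validation protocol over a parameter grid: for every
#' combination of network size, sample size, significance level, estimator
#' and seed, generate a random ground-truth network, simulate the dynamics,
#' infer the network, and score it. Completed cells found in `out_dir` are
#' skipped, so an interrupted suite can be resumed; the merged table is
#' independent of execution order.
#'
#' @param N_list,T_list,alpha_list,estimator_list,seed_list Grid axes.
#' @param dynamics `"var"` or `"clm"`.
#' @param p_link Link probability (default `3/N`).
#' @param settings Baseline [inference_settings()]; alpha/estimator/seed are
#'   overridden per cell.
#' @param out_dir Optional directory for per-cell CSV rows and the merged
#'   score table.
#' @return Data frame with one row per cell: N, T, alpha, estimator, seed,
#'   dynamics, precision, recall, specificity, lag_error.
#' @export
run_replication_suite <- function(N_list, T_list, alpha_list = 0.001,
                                  estimator_list = "gaussian",
                                  seed_list = 1:10, dynamics = c("var", "clm"),
                                  p_link = NULL,
                                  settings = inference_settings(),
                                  out_dir = NULL) {
  dynamics <- match.arg(dynamics)
  grid <- expand.grid(N = N_list, T = T_list, alpha = alpha_list,
                      estimator = estimator_list, seed = seed_list,
                      stringsAsFactors = FALSE)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    cell_id <- sprintf("%s_N%d_T%d_a%g_%s_s%d", dynamics, g$N, g$T,
                       g$alpha, g$estimator, g$seed)
    cell_file <- if (!is.null(out_dir))
      file.path(out_dir, paste0(cell_id, ".csv"))
    if (!is.null(cell_file) && file.exists(cell_file)) {
      rows[[i]] <- utils::read.csv(cell_file)
      next
    }
    rows[[i]] <- tryCatch({
      s <- settings
      s$alpha <- g$alpha
      s$estimator <- g$estimator
      s$analytic <- g$estimator == "gaussian"
      s$seed <- g$seed
      p <- if (is.null(p_link)) 3 / g$N else p_link
      net <- random_var_network(g$N, p = p, seed = child_seed(g$seed, g$N, 17L))
      dat <- if (dynamics == "var")
        simulate_var(net, g$T, seed = child_seed(g$seed, g$N, 29L))
      else simulate_clm(net, g$T, seed = child_seed(g$seed, g$N, 29L))
      res <- infer_network(dat, s)
      sc <- classification_scores(confusion_counts(res, net))
      le <- relative_lag_error(res, net)
      row <- data.frame(N = g$N, T = g$T, alpha = g$alpha,
                        estimator = g$estimator, seed = g$seed,
                        dynamics = dynamics,
                        precision = sc$precision, recall = sc$recall,
                        specificity = sc$specificity,
                        lag_error = le$relative_error)
      if (!is.null(cell_file)) utils::write.csv(row, cell_file,
                                                row.names = FALSE)
      row
    }, error = function(e) {
      data.frame(N = g$N, T = g$T, alpha = g$alpha, estimator = g$estimator,
                 seed = g$seed, dynamics = dynamics, precision = NA_real_,
                 recall = NA_real_, specificity = NA_real_,
                 lag_error = NA_real_)
    })
  }
  out <- do.call(rbind, rows)
  if (!is.null(out_dir))
    utils::write.csv(out, file.path(out_dir, "scores.csv"), row.names = FALSE)
  out
}
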