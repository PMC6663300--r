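st_gauss <- inference_settings(alpha = 0.05)

test_that("target-past selection finds the AR(1) self-memory at lag 1", {
  net <- empty_network(1, beta = 0.5)
  dat <- simulate_var(net, 10000, seed = 101)
  # need >= 2 processes for an engine; add an independent noise process
  dat2 <- cbind(dat[, 1, 1], withr::with_seed(102, rnorm(10000)))
  sel <- select_target_past(dat2, 1, st_gauss)
  expect_gte(nrow(sel$selected), 1)
  expect_equal(sel$selected$process[1], 1)
  expect_equal(sel$selected$lag[1], 1)
  # a target whose candidate set starts empty selects nothing and runs no test
  s0 <- inference_settings(alpha = 0.05, l_target = 1)
  white <- withr::with_seed(103, matrix(rnorm(4000), ncol = 2))
  selw <- select_target_past(white, 1, s0)
  expect_lte(nrow(selw$selected), 1)
})

test_that("source selection recovers a lag-2 coupling and its lag", {
  net <- two_node_net(lag = 2L)
  dat <- simulate_var(net, 10000, seed = 111)
  tp <- select_target_past(dat, 2, st_gauss)
  src <- select_source_past(dat, 2, tp$selected, st_gauss)
  expect_true(any(src$selected$process == 1 & src$selected$lag == 2))
})

test_that("common-driver sources are rejected as redundant", {
  # Z (node 1) drives X (node 2) and Y (node 3); X must not enter Y's set
  adj <- matrix(FALSE, 3, 3); adj[1, 2] <- adj[1, 3] <- TRUE
  net <- assign_couplings(adj, seed = 2)
  net$lags[1, 2] <- 1L; net$lags[1, 3] <- 1L
  hits <- sapply(1:8, function(s) {
    dat <- simulate_var(net, 5000, seed = 120 + s)
    res <- infer_target(dat, 3, st_gauss)
    any(res$selected_sources_past$process == 2)
  })
  expect_lte(mean(hits), 0.25)
  # and the true driver is found every time
  dat <- simulate_var(net, 5000, seed = 121)
  res <- infer_target(dat, 3, st_gauss)
  expect_true(any(res$selected_sources_past$process == 1))
})

test_that("pruning removes a duplicated (redundant) source variable", {
  # node 1 drives node 3; node 2 is a jittered copy of node 1, so the two
  # candidate variables carry the same information about the target
  net <- two_node_net(lag = 1L)
  dat <- simulate_var(net, 5000, seed = 131)
  copy <- dat[, 1, 1] + withr::with_seed(132, rnorm(5000, sd = 1e-4))
  dat3 <- cbind(dat[, 1, 1], copy, dat[, 2, 1])
  # the two duplicate statistics are nearly identical, so the minimum is not
  # an extreme of independent nulls; a strict level keeps the spurious
  # retention probability (about sqrt(alpha)) low
  st <- inference_settings(alpha = 0.001)
  tp <- select_target_past(dat3, 3, st)
  forced <- data.frame(process = c(1L, 2L), lag = c(1L, 1L))
  pr <- prune_sources(dat3, 3, tp$selected, forced, st)
  expect_equal(nrow(pr$selected), 1)
  expect_equal(nrow(pr$removed), 1)
  # a genuinely contributing variable survives with p ~ 0
  pr1 <- prune_sources(dat3, 3, tp$selected,
                       data.frame(process = 1L, lag = 1L), st)
  expect_equal(nrow(pr1$selected), 1)
})

test_that("pruning with an empty source set is a no-op", {
  white <- withr::with_seed(141, matrix(rnorm(2000), ncol = 2))
  pr <- prune_sources(white, 1, data.frame(process = integer(0), lag = integer(0)),
                      data.frame(process = integer(0), lag = integer(0)),
                      st_gauss)
  expect_equal(nrow(pr$selected), 0)
  expect_equal(nrow(pr$removed), 0)
})

test_that("white-noise targets select no sources at about the nominal rate", {
  # per-target false positive rate ~ alpha under the complete null
  picks <- sapply(1:40, function(s) {
    white <- withr::with_seed(150 + s, matrix(rnorm(3 * 600), ncol = 3))
    res <- infer_target(white, 1, st_gauss)
    nrow(res$selected_sources_past) > 0
  })
  expect_lte(mean(picks), 0.2)
})

test_that("incremental contributions sum to the collective transfer entropy", {
  # greedy chain consistency for the Gaussian estimator (shared covariance)
  net <- random_var_network(6, p = 0.4, seed = 161)
  dat <- simulate_var(net, 8000, seed = 162)
  res <- infer_target(dat, 2, inference_settings(alpha = 0.001))
  if (nrow(res$selected_sources_past) > 0 &&
      nrow(res$removed_in_pruning) == 0 && !res$rejected_by_omnibus) {
    tr <- res$trace$sources
    inc <- sum(tr$cmi[tr$significant])
    expect_equal(inc, res$omnibus_te, tolerance = 1e-8)
  }
  expect_false(is.na(res$omnibus_p))
})

test_that("inference is deterministic and order-independent across targets", {
  net <- random_var_network(5, p = 0.4, seed = 171)
  dat <- simulate_var(net, 2000, seed = 172)
  st <- inference_settings(alpha = 0.01, seed = 99)
  a <- infer_network(dat, st)
  b <- infer_network(dat, st)
  expect_identical(a$links, b$links)
  cpar <- infer_network(dat, st, workers = 2)
  expect_identical(a$links, cpar$links)
  # target sharding: merging two shards equals the full run
  sh1 <- infer_network(dat, st, targets = 1:2)
  sh2 <- infer_network(dat, st, targets = 3:5)
  expect_identical(a$fdr$omnibus_p,
                   c(sh1$fdr$omnibus_p, sh2$fdr$omnibus_p))
})

test_that("surrogate-based inference recovers a strong coupling (Gaussian)", {
  net <- two_node_net(lag = 1L)
  dat <- simulate_var(net, 2000, seed = 181)
  st <- inference_settings(alpha = 0.05, S = 100, analytic = FALSE,
                           seed = 42)
  res <- infer_network(dat, st)
  expect_true(any(res$links$source == 1 & res$links$target == 2))
  # deterministic given the master seed
  res2 <- infer_network(dat, st)
  expect_identical(res$links, res2$links)
})

test_that("KSG-based inference detects a logistic-map coupling", {
  net <- two_node_net(lag = 1L)
  dat <- simulate_clm(net, 400, seed = 191)
  st <- inference_settings(alpha = 0.05, S = 50, estimator = "ksg",
                           l_target = 2, l_sources = 2, seed = 7)
  res <- infer_network(dat, st)
  expect_true(any(res$links$source == 1 & res$links$target == 2))
  expect_false(any(res$links$source == 2 & res$links$target == 1))
})

test_that("selected and candidate sets stay disjoint and duplicate-free", {
  net <- random_var_network(6, p = 0.4, seed = 201)
  dat <- simulate_var(net, 3000, seed = 202)
  res <- infer_target(dat, 4, st_gauss)
  sel <- rbind(res$selected_sources_past[c("process", "lag")],
               res$selected_target_past[c("process", "lag")])
  expect_equal(anyDuplicated(sel), 0)
  expect_false(any(res$selected_sources_past$process == 4))
  expect_true(all(res$selected_target_past$process == 4))
  expect_true(all(res$selected_sources_past$lag >= 1 &
                    res$selected_sources_past$lag <= 5))
})

test_that("omnibus rejection empties the source set but keeps its p value", {
  # force a spurious source into an otherwise null system at loose alpha:
  # run many nulls and check that any reported link always has omnibus p < alpha
  for (s in 1:10) {
    white <- withr::with_seed(210 + s, matrix(rnorm(2 * 500), ncol = 2))
    res <- infer_target(white, 1, inference_settings(alpha = 0.3))
    if (res$rejected_by_omnibus) {
      expect_equal(nrow(res$selected_sources_past), 0)
      expect_gte(res$omnibus_p, 0.3)
    } else if (nrow(res$selected_sources_past) > 0) {
      expect_lt(res$omnibus_p, 0.3)
    }
  }
})
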