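test_that("candidate surrogates permute only the candidate and preserve its marginal", {
  col <- withr::with_seed(1, rnorm(200))
  s1 <- withr::with_seed(2, generate_candidate_surrogate(col))
  expect_setequal(s1, col)
  # seeded determinism
  s2 <- withr::with_seed(2, generate_candidate_surrogate(col))
  expect_identical(s1, s2)
  # replication-block shuffling keeps within-block order
  repid <- rep(1:4, each = 50)
  s3 <- withr::with_seed(3,
    generate_candidate_surrogate(col, repid, mode = "shuffle_replications", S = 10))
  blocks <- split(col, repid)
  sblocks <- split(s3, rep(1:4, each = 50))
  expect_true(all(vapply(sblocks, function(b)
    any(vapply(blocks, identical, logical(1), b)), logical(1))))
  expect_error(
    generate_candidate_surrogate(col, mode = "shuffle_replications"),
    "shuffle_embedded_samples")
})

test_that("permutation destroys source-target coupling", {
  xy <- rbvn(1500, 0.8, seed = 4)
  obs <- gaussian_cmi(xy[, 1], xy[, 2])$value
  surr <- withr::with_seed(5, replicate(200,
    gaussian_cmi(generate_candidate_surrogate(xy[, 1]), xy[, 2])$value))
  expect_gt(obs, stats::quantile(surr, 0.975))
})

test_that("maximum statistic test handles extreme observations", {
  surr <- matrix(rnorm(3 * 100), 3, 100)
  up <- max_statistic_test(c(0.1, 99, 0.2), alpha = 0.05, surrogate_cmis = surr)
  expect_equal(up$p_value, 0)
  expect_true(up$significant)
  expect_equal(up$which_max, 2L)
  down <- max_statistic_test(c(-1, -2), alpha = 0.05,
                             surrogate_cmis = abs(surr[1:2, ]))
  expect_equal(down$p_value, 1)
  expect_false(down$significant)
  expect_error(max_statistic_test(numeric(0), alpha = 0.05), "empty")
})

test_that("minimum statistic test retains strong and removes null minima", {
  surr <- matrix(rnorm(2 * 100, sd = 0.01), 2, 100)
  strong <- min_statistic_test(c(0.5, 0.6), alpha = 0.05, surrogate_cmis = surr)
  expect_equal(strong$p_value, 0)   # no surrogate minimum exceeds 0.5
  expect_true(strong$significant)
  # observed minimum below every surrogate minimum -> p = 1 -> removal
  weak <- min_statistic_test(c(-5, 0.6), alpha = 0.05, surrogate_cmis = surr)
  expect_equal(weak$p_value, 1)
  expect_false(weak$significant)
  expect_equal(weak$which_min, 1L)
})

test_that("p-values are nonincreasing in the observed statistic", {
  surr <- matrix(withr::with_seed(6, rnorm(5 * 400)), 5, 400)
  stats_grid <- seq(-2, 2, length.out = 21)
  pmax_grid <- sapply(stats_grid, function(s)
    max_statistic_test(c(rep(-10, 4), s), alpha = 0.05,
                       surrogate_cmis = surr)$p_value)
  expect_true(all(diff(pmax_grid) <= 0))
  pom <- sapply(stats_grid, function(s)
    omnibus_test(s, alpha = 0.05, null_values = surr[1, ])$p_value)
  expect_true(all(diff(pom) <= 0))
})

test_that("surrogate and analytic maximum-statistic p values agree for Gaussian data", {
  # moderate dependence so the p value is away from 0 and 1
  M <- 800
  y <- withr::with_seed(7, rnorm(M))
  cands <- withr::with_seed(8,
    cbind(0.07 * y + rnorm(M), rnorm(M), rnorm(M)))
  obs <- apply(cands, 2, function(cc) gaussian_cmi(cc, y)$value)
  surr <- withr::with_seed(9, {
    t(apply(cands, 2, function(cc) {
      replicate(10000, {
        r <- stats::cor(sample(cc), y)
        -0.5 * log(1 - r^2)
      })
    }))
  })
  emp <- max_statistic_test(obs, alpha = 0.05, surrogate_cmis = surr)
  ana <- max_statistic_test(obs, alpha = 0.05, M = M)
  expect_gt(emp$p_value, 0.001)  # non-degenerate configuration
  expect_equal(emp$p_value, ana$p_value, tolerance = 0.01 / max(ana$p_value, 0.01))
})

test_that("analytic maximum statistic controls the FWER over 9 white-noise candidates", {
  M <- 500
  rate <- withr::with_seed(10, mean(replicate(1000, {
    y <- rnorm(M)
    cands <- matrix(rnorm(M * 9), M, 9)
    obs <- -0.5 * log(1 - stats::cor(cands, y)^2)
    max_statistic_test(as.numeric(obs), alpha = 0.05, M = M)$significant
  })))
  expect_equal(rate, 0.05, tolerance = 0.015 / 0.05)
})

test_that("Dunn-Sidak single-variable rate matches its closed form and bounds", {
  expect_equal(vfpr_from_alpha(0.05, 1), 0.05)
  expect_equal(vfpr_from_alpha(0.05, 10), 1 - 0.95^(1 / 10), tolerance = 1e-12)
  expect_equal(vfpr_from_alpha(0.05, 10), 0.005116, tolerance = 1e-4 / 0.005)
  # always at least the Bonferroni rate, decreasing in n, increasing in alpha
  for (n in c(1, 2, 5, 20, 100))
    expect_gte(vfpr_from_alpha(0.05, n), 0.05 / n)
  v <- sapply(c(1, 2, 5, 20), vfpr_from_alpha, alpha_max = 0.05)
  expect_true(all(diff(v) < 0))
  expect_lt(vfpr_from_alpha(0.01, 7), vfpr_from_alpha(0.05, 7))
  # first-order approximation alpha/n as alpha -> 0
  expect_equal(vfpr_from_alpha(1e-8, 13) / (1e-8 / 13), 1, tolerance = 1e-6)
  expect_error(vfpr_from_alpha(0, 5))
})

test_that("per-target FWER matches the geometric-sum closed form", {
  expect_equal(tfpr_from_alpha(0.3, 1), 0.3)
  expect_equal(tfpr_from_alpha(0.5, 2), 0.75)
  # direct summation oracle
  a <- 0.037; n <- 23
  expect_equal(tfpr_from_alpha(a, n), sum(a^(1:n)), tolerance = 1e-12)
  # small-alpha approximation: tFPR ~ alpha within 0.1%
  expect_equal(tfpr_from_alpha(0.001, 100), 0.001, tolerance = 0.001)
})

test_that("FDR combination matches brute-force Benjamini-Hochberg", {
  expect_equal(fdr_combine_targets(rep(1, 5), 0.05), rep(FALSE, 5))
  expect_equal(fdr_combine_targets(0.01, 0.05), TRUE)
  # 0.04 > 2 * 0.05 / 3: only the smallest p survives step-up
  expect_equal(fdr_combine_targets(c(0.001, 0.04, 0.9), 0.05),
               c(TRUE, FALSE, FALSE))
  # property: agreement with the step-up definition, invariant to ordering
  withr::with_seed(12, {
    for (i in 1:50) {
      p <- runif(sample(1:12, 1))^sample(1:3, 1)
      q <- runif(1, 0.01, 0.2)
      expect_equal(fdr_combine_targets(p, q), bh_oracle(p, q))
      ord <- sample(length(p))
      expect_equal(fdr_combine_targets(p[ord], q),
                   bh_oracle(p, q)[ord])
    }
  })
})
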