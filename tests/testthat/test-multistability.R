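test_that("column standardisation follows the sample-variance convention", {
  expect_equal(standardise_columns(matrix(c(0, 1), 2)),
               matrix(c(-1, 1) / sqrt(2), 2))
  expect_equal(standardise_columns(matrix(0.5, 3, 1)), matrix(0, 3, 1))
  set.seed(12)
  m <- matrix(runif(200), 20)
  std <- standardise_columns(m)
  expect_true(all(abs(colMeans(std)) < 1e-12))
  expect_true(all(abs(apply(std, 2, sd) - 1) < 1e-12))
  # resolution floor: tiny-variance columns are treated as constant
  m[, 3] <- 0.7 + rnorm(20, sd = 1e-4)
  std <- standardise_columns(m, min_sd = 0.01)
  expect_equal(std[, 3], rep(0, 20))
  expect_equal(abs(apply(std[, -3], 2, sd)), rep(1, 9), tolerance = 1e-12)
})

test_that("ensembles have one pattern row per seeded run", {
  net <- fixture_net_8()
  sys <- build_system(net, sample_frequencies(8, seed = 2))
  ens <- run_ensemble(sys, n_runs = 5, seed = 3, n_steps = 600)
  expect_equal(dim(ens), c(5, 28))
  expect_true(all(ens >= 0 & ens <= 1))
  expect_identical(unclass(ens),
                   unclass(run_ensemble(sys, n_runs = 5, seed = 3,
                                        n_steps = 600)))
  # identical initial phases give identical patterns (noise-free dynamics)
  tr1 <- simulate_phases(sys, seed = 9)
  tr2 <- simulate_phases(sys, seed = 9)
  expect_identical(unclass(sync_pattern(tr1)), unclass(sync_pattern(tr2)))
})

test_that("a 2-node system always reaches the same synchronisation state", {
  w <- matrix(c(0, 0.1, 0.1, 0), 2)
  l <- matrix(c(0, 30, 30, 0), 2)
  sys <- build_system(structural_network(w, l), c(40, 42))
  ens <- run_ensemble(sys, n_runs = 8, seed = 5)
  expect_lt(max(ens) - min(ens), 0.01)
  res <- assess_multistability(sys, n_runs = 8, seed = 5, n_reference = 10)
  expect_equal(res$optimal_k, 1L)
  expect_false(res$multistable)
})

test_that("gap statistic handles degenerate and structured data sanely", {
  flat <- matrix(0.3, 20, 10)
  g <- gap_statistic_k(flat, k_max = 4, seed = 1)
  expect_equal(g$optimal_k, 1L)
  expect_true(attr(g, "degenerate"))

  blobs <- make_blobs(rbind(rep(0, 5), rep(4, 5)), 60, seed = 21)
  g2 <- gap_statistic_k(standardise_columns(blobs$x), k_max = 5,
                        n_reference = 30, seed = 2)
  expect_equal(g2$optimal_k, 2L)
  # fitted within-dispersion is non-increasing in k
  expect_true(all(diff(g2$gap_curve$logW) < 1e-8))
  expect_error(gap_statistic_k(flat, k_max = 30), "exceeds")
})

test_that("assessment output satisfies its structural contracts", {
  net <- fixture_net_8()
  sys <- build_system(net, sample_frequencies(8, seed = 41))
  res <- assess_multistability(sys, n_runs = 10, n_reference = 15, seed = 6)
  expect_lte(res$optimal_k, 6L)
  expect_equal(sort(unique(res$labels)), seq_len(res$optimal_k))
  pc <- res$pattern_correlation
  expect_equal(dim(pc), c(10, 10))
  expect_equal(diag(pc), rep(1, 10))
  expect_equal(pc, t(pc), tolerance = 1e-12)
  # end-to-end seeded determinism
  res2 <- assess_multistability(sys, n_runs = 10, n_reference = 15, seed = 6)
  expect_identical(res$optimal_k, res2$optimal_k)
  expect_identical(res$labels, res2$labels)
  expect_equal(res$pattern_correlation, res2$pattern_correlation)
})

test_that("row correlations tolerate zero-variance patterns", {
  m <- rbind(rep(1, 6), rep(1, 6), c(1:6) / 6)
  cc <- strobosync:::row_correlation(m)
  expect_equal(cc[1, 2], 1) # identical constant rows
  expect_equal(cc[1, 3], 0) # constant vs varying: no measurable association
  expect_equal(diag(cc), rep(1, 3))
})
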