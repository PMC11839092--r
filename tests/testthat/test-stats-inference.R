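# Paired t maps, cluster permutation tests, Bonferroni channel tests,
# empirical chance levels, behavioural tests.

test_that("dependent_t_map matches the direct paired-t formula oracle", {
  # 5-subject toy set, one cell
  a <- c(3.1, 2.8, 3.6, 3.0, 3.3)
  b <- c(2.9, 2.7, 3.1, 3.2, 2.8)
  d <- a - b
  oracle <- mean(d) * sqrt(5) / sd(d)
  got <- dependent_t_map(matrix(a, 5, 1), matrix(b, 5, 1))
  expect_equal(as.numeric(got), oracle, tolerance = 1e-12)
  # and against stats::t.test as an independent implementation
  expect_equal(as.numeric(got), unname(t.test(a, b, paired = TRUE)$statistic),
               tolerance = 1e-12)
  # identical arrays -> all zero
  arr <- array(rnorm(5 * 4 * 3), c(5, 4, 3))
  expect_true(all(dependent_t_map(arr, arr) == 0))
  # constant nonzero difference -> signed Inf sentinel
  expect_identical(as.numeric(dependent_t_map(matrix(2, 4, 1),
                                              matrix(1, 4, 1))), Inf)
  expect_error(dependent_t_map(matrix(1, 3, 2), matrix(1, 3, 3)),
               class = "trfcomp_invalid_argument")
})

test_that("adjacency graph is symmetric with no self-neighbours", {
  adj <- adjacency_graph()
  expect_true(isSymmetric(adj$matrix))
  expect_true(all(!diag(adj$matrix)))
  expect_equal(rownames(adj$matrix), adj$channels)
})

test_that("identical conditions produce no clusters", {
  adj <- central_adjacency()
  arr <- array(rnorm(8 * 10 * 10), c(8, 10, 10))
  ct <- cluster_permutation_test(arr, arr, adj,
                                 permutation_config(100, min_neighbors = 1,
                                                    seed = 1))
  expect_length(ct$clusters, 0)
  expect_equal(nrow(ct$significant_intervals), 0)
})

test_that("cluster membership is contiguous in time and connected in space", {
  adj <- central_adjacency()
  set.seed(21)
  n <- 10
  base <- array(rnorm(n * 15 * 10, sd = 0.5), c(n, 15, 10))
  eff <- array(rnorm(n * 15 * 10, sd = 0.5), c(n, 15, 10))
  eff[, 5:8, 1:6] <- eff[, 5:8, 1:6] + 2
  ct <- cluster_permutation_test(eff, base, adj,
                                 permutation_config(200, min_neighbors = 1,
                                                    seed = 99))
  expect_gt(length(ct$clusters), 0)
  for (cl in ct$clusters) {
    # temporal contiguity: per channel, member lags form runs linked
    # through spatially adjacent channels; check the cluster's overall lag
    # span has no gap not covered by any member
    expect_true(all(diff(sort(unique(cl$lags))) <= 1))
    # spatial connectivity: every member channel has a neighbour (or
    # time-adjacent same-channel sample) inside the cluster
    A <- adj$matrix
    for (ch in unique(cl$channels)) {
      others <- unique(cl$channels)
      expect_true(length(others) == 1 || any(A[ch, others]))
    }
  }
})

test_that("an injected effect is detected where it was injected", {
  adj <- central_adjacency()
  detected <- overlap <- logical(20)
  for (r in 1:20) {
    set.seed(3000 + r)
    n <- 12
    noise <- function() array(rnorm(n * 20 * 10, sd = 0.3), c(n, 20, 10))
    a <- noise(); b <- noise()
    a[, 8:12, ] <- a[, 8:12, ] + 1.5        # strong N1-window-like offset
    ct <- cluster_permutation_test(a, b, adj,
                                   permutation_config(200, min_neighbors = 1,
                                                      seed = 7000 + r),
                                   lags_s = seq(0, 0.19, by = 0.01))
    sig <- Filter(function(cl) cl$significant, ct$clusters)
    detected[r] <- length(sig) > 0
    overlap[r] <- any(vapply(sig, function(cl)
      cl$start_s <= 0.11 && cl$end_s >= 0.08, logical(1)))
  }
  expect_gte(mean(detected & overlap), 0.9)
})

test_that("permutation p-values are invariant to condition relabelling", {
  adj <- central_adjacency()
  set.seed(31)
  n <- 8
  a <- array(rnorm(n * 12 * 10), c(n, 12, 10))
  b <- array(rnorm(n * 12 * 10, mean = 0.5), c(n, 12, 10))
  cfg <- permutation_config(150, min_neighbors = 1, seed = 5)
  ab <- cluster_permutation_test(a, b, adj, cfg)
  ba <- cluster_permutation_test(b, a, adj, cfg)
  expect_equal(sort(vapply(ab$clusters, `[[`, numeric(1), "mass")),
               sort(-vapply(ba$clusters, `[[`, numeric(1), "mass")),
               tolerance = 1e-10)
  # sign-flip null is symmetric, so the null distributions agree exactly
  expect_equal(ab$null_max_mass, ba$null_max_mass, tolerance = 1e-10)
})

test_that("few subjects trigger the exact-enumeration fallback with a warning", {
  adj <- central_adjacency()
  a <- array(rnorm(2 * 6 * 10), c(2, 6, 10))
  b <- array(rnorm(2 * 6 * 10), c(2, 6, 10))
  expect_warning(
    ct <- cluster_permutation_test(a, b, adj,
                                   permutation_config(100, min_neighbors = 1)),
    "exact enumeration")
  expect_true(ct$exact_enumeration)
  expect_length(ct$null_max_mass, 4)         # 2^2 sign patterns
})

test_that("bonferroni_channel_tests matches the direct formula oracle", {
  set.seed(17)
  n <- 8
  mapA <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  mapB <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  res <- bonferroni_channel_tests(mapA, mapB, N = 4)
  for (j in 1:4) {
    tt <- t.test(mapA[, j], mapB[, j], paired = TRUE)
    expect_equal(res$t[j], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p_corrected[j], min(1, tt$p.value * 4), tolerance = 1e-10)
  }
  # printed-arithmetic cases: p 0.01 x 64 = 0.64 ns; 0.0005 x 64 = 0.032 sig
  expect_false(0.01 * 64 < 0.05)
  expect_true(min(1, 0.0005 * 64) < 0.05)
})

test_that("empirical_chance_level reproduces exact binomial thresholds", {
  expect_equal(empirical_chance_level(1, 2, 0.05), 100)
  expect_equal(empirical_chance_level(10, 2, 0.05), 80)  # k = 8
  expect_equal(empirical_chance_level(30, 2, 0.05), 100 * 19 / 30)
  # qbinom as the independent oracle over a range of n
  for (n in 5:100)
    expect_equal(empirical_chance_level(n, 2, 0.05),
                 100 * qbinom(0.95, n, 0.5) / n)
  # coarse decreasing trend (the pointwise monotonicity claim fails at
  # n = 5 -> 6, where the threshold k jumps; see the methods vignette)
  expect_lt(empirical_chance_level(100), empirical_chance_level(30))
  expect_lt(empirical_chance_level(30), empirical_chance_level(10))
})

test_that("paired_behavioral_test matches the formula oracle and degenerate contracts", {
  accA <- c(80, 85, 78, 90, 84, 88)
  accB <- c(75, 80, 80, 85, 80, 82)
  res <- paired_behavioral_test(accA, accB)
  tt <- t.test(accA, accB, paired = TRUE)
  expect_equal(res$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-12)
  # identities
  expect_equal(paired_behavioral_test(accA, accA)[c("t", "p_value")],
               list(t = 0, p_value = 1))
  expect_equal(paired_behavioral_test(c(1, 0), c(0, 1))$t, 0)
  expect_identical(paired_behavioral_test(c(2, 2), c(1, 1))$t, Inf)
})
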