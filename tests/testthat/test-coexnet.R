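test_that("equal-frequency discretization balances occupancy", {
  b <- discretize_equal_frequency(matrix(c(1, 2, 3, 4), 1, 4), 2)
  expect_equal(unname(b$bins[1, ]), c(1, 1, 2, 2))
  expect_equal(b$scheme, "equal-frequency")

  cons <- discretize_equal_frequency(matrix(5, 1, 6), 2)
  expect_true(all(cons$bins == 1))

  ties <- discretize_equal_frequency(matrix(c(1, 1, 2, 2), 1, 4), 2)
  expect_equal(as.integer(table(ties$bins[1, ])), c(2L, 2L))

  # tie-free values: occupancies differ by at most 1, any n and bins
  set.seed(2)
  for (n in c(9, 16, 25)) {
    x <- matrix(rnorm(3 * n), 3, n)
    bb <- discretize_equal_frequency(x)
    occ <- apply(bb$bins, 1, function(r) range(table(r)))
    expect_true(all(occ[2, ] - occ[1, ] <= 1))
  }
  expect_error(discretize_equal_frequency(matrix(1:4, 1, 4), 1), "at least 2")
  expect_error(discretize_equal_frequency(matrix(1:3, 1, 3), 4), "samples")
})

test_that("plug-in mutual information matches hand evaluation", {
  x <- c(1, 1, 2, 2)
  expect_equal(mutual_information(x, x), 1)  # perfect binary dependence
  expect_equal(mutual_information(x, rep(1, 4)), 0)  # constant partner

  # joint table [[2,1],[1,2]] over n = 6
  a <- c(1, 1, 1, 2, 2, 2)
  b <- c(1, 1, 2, 1, 2, 2)
  hand <- (2 / 3) * log2(4 / 3) + (1 / 3) * log2(2 / 3)
  expect_equal(mutual_information(a, b), hand, tolerance = 1e-12)

  expect_equal(mutual_information(a, b), mutual_information(b, a))
  expect_error(mutual_information(1:4, 1:5), "equal length")
})

test_that("pairwise MI covers all pairs and respects invariances", {
  set.seed(11)
  x <- matrix(rnorm(4 * 25), 4, 25, dimnames = list(letters[1:4], NULL))
  b <- discretize_equal_frequency(x)
  M <- pairwise_mi(b)
  expect_equal(dim(M), c(4, 4))
  expect_equal(M, t(M))
  expect_equal(sum(upper.tri(M)), 6)  # 4 genes -> 6 unordered pairs

  # scalar estimator agrees with the compiled kernel
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(M[i, j], mutual_information(b$bins[i, ], b$bins[j, ]),
                 tolerance = 1e-12)
  }

  # self-similarity bound: MI(x, x) >= MI(x, y)
  expect_true(all(diag(M) >= M - 1e-12))

  # permuting samples identically leaves every value unchanged
  perm <- sample(25)
  b2 <- b
  b2$bins <- b$bins[, perm]
  expect_equal(pairwise_mi(b2), M, tolerance = 1e-12)

  # a duplicated gene attains the maximal MI of its row
  x2 <- rbind(x, dup = x[1, ])
  M2 <- pairwise_mi(discretize_equal_frequency(x2))
  expect_equal(M2["a", "dup"], max(M2["a", colnames(M2) != "a"]))
})

test_that("analytic MI significance follows the chi-squared G identity", {
  expect_equal(mi_significance(0, 100, 2, 2), 1)

  mi <- (2 / 3) * log2(4 / 3) + (1 / 3) * log2(2 / 3)  # approx 0.0817 bits
  g <- 2 * 100 * log(2) * mi
  expect_equal(g, 11.33, tolerance = 1e-3)
  expect_equal(mi_significance(mi, 100, 2, 2),
               pchisq(g, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(mi_significance(mi, 100, 2, 2), 7.6e-4, tolerance = 0.01)

  # at n = 174 and 13 x 13 bins, p decreases in MI and reaches < 1e-30
  mis <- seq(0.1, 3, length.out = 30)
  ps <- mi_significance(mis, 174, 13, 13)
  expect_true(all(diff(ps) < 0))
  expect_lt(min(ps), 1e-30)
  expect_error(mi_significance(0.1, 0, 2, 2), "positive")
})

test_that("percentile thresholding keeps the inclusive top tail", {
  set.seed(12)
  g <- 46  # 46 * 45 / 2 = 1035 unordered pairs
  M <- matrix(0, g, g, dimnames = list(paste0("g", 1:g), paste0("g", 1:g)))
  ut <- which(upper.tri(M))
  tie_free <- sample(seq(0.001, 1, length.out = length(ut)))
  M[ut] <- tie_free
  M <- M + t(M)
  # with 1035 tie-free values the 99th percentile keeps ceiling(1%) = 11
  net <- threshold_at_percentile(M, 99)
  expect_equal(nrow(net$edges), sum(tie_free >= net$threshold_value))
  expect_lte(nrow(net$edges), ceiling(0.011 * length(ut)))
  expect_true(all(net$edges$weight >= net$threshold_value))
  expect_equal(net$percentile, 99)

  # exactly 1000 tie-free values -> exactly 10 edges survive
  v1000 <- seq_len(1000) / 1000
  thr <- unname(quantile(v1000, 0.99, type = 7))
  expect_equal(sum(v1000 >= thr), 10)

  # all-equal values: the >= rule keeps every edge
  Meq <- matrix(0.5, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(Meq) <- 1
  net_eq <- threshold_at_percentile(Meq, 99)
  expect_equal(nrow(net_eq$edges), 10)
})

test_that("network inference recovers planted modules from counts", {
  p <- sim_params(n_genes = 200, n_modules = 5, module_size = 20,
                  factor_loading = 0.8, de_fraction = 0, n_early = 0,
                  n_late = 100, seed = 31)
  tr <- simulate_truth(p)
  d <- assign_cohorts(seq(70, 95, length.out = 100))
  lc <- cpm(simulate_counts(tr, d, p), log = TRUE)
  net <- build_coexpression_network(lc, percentile = 99)
  m <- tr$module_of
  intra <- m[net$edges$from] == m[net$edges$to] &
    m[net$edges$from] != "background"
  expect_gte(mean(intra), 0.8)
  expect_equal(net$n_samples, 100)
  expect_equal(net$n_bins, 10)
  # edge p-values are provenance, not a filter: all edges above threshold stay
  expect_true(all(net$edges$weight >= net$threshold_value))
})
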