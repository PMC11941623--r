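test_that("expression filter applies the CPM rule inclusively", {
  # libraries of 1e6 reads make counts equal CPM, so the rule is legible
  cts <- rbind(
    g1 = c(0, 0, 0, 0),        # all zero: removed for any min_cpm > 0
    g2 = c(1, 1, 0, 0),        # CPM >= 1 in exactly 2 samples: kept
    g3 = c(5, 8, 2, 1),        # comfortably kept
    g4 = c(0, 0, 3, 0),        # 1 qualifying sample: removed
    g5 = c(0.6, 0.4, 0.2, 0.9) # never reaches 1 CPM: removed
  )
  m <- rbind(cts, 1e6 - matrix(colSums(cts), 1))
  rownames(m) <- c(rownames(cts), "filler")
  colnames(m) <- paste0("s", 1:4)
  kept <- filter_low_expression(m, min_cpm = 1, min_samples = 2)
  expect_setequal(rownames(kept), c("g2", "g3", "filler"))
  expect_error(filter_low_expression(m, 1, 10), "min_samples")
  expect_warning(filter_low_expression(m, min_cpm = 2e6, min_samples = 1),
                 "no genes")
})

test_that("TMM factors are 1 for proportional samples", {
  set.seed(10)
  a <- rpois(200, 100) + 1L
  m <- cbind(A = a, B = a, C = 3L * a)
  rownames(m) <- paste0("g", 1:200)
  f <- compute_tmm_factors(m)
  expect_equal(f$tmm_factor, rep(1, 3), tolerance = 1e-12)
  expect_equal(exp(mean(log(f$tmm_factor))), 1, tolerance = 1e-12)
})

test_that("TMM matches a spreadsheet evaluation on an inflated-gene fixture", {
  # 8 genes, two samples; g8 is inflated 20x in B
  yA <- c(100, 200, 300, 400, 500, 600, 700, 100)
  yB <- c(100, 200, 300, 400, 500, 600, 700, 2000)
  m <- cbind(A = yA, B = yB)
  rownames(m) <- paste0("g", 1:8)
  f <- compute_tmm_factors(m, trim_m = 0.30, trim_a = 0.05)

  # independent evaluation of the trimmed weighted mean of M values,
  # with sample A as reference (A has the 75th-percentile CPM closer to
  # the column mean of those percentiles)
  nA <- sum(yA); nB <- sum(yB)
  M <- log2((yB / nB) / (yA / nA))
  A <- 0.5 * log2((yB / nB) * (yA / nA))
  w <- 1 / ((nB - yB) / (nB * yB) + (nA - yA) / (nA * yA))
  keepM <- rank(M) >= floor(8 * 0.3) + 1 & rank(M) <= 8 - floor(8 * 0.3)
  keepA <- rank(A) >= floor(8 * 0.05) + 1 & rank(A) <= 8 - floor(8 * 0.05)
  fB <- 2^(sum(w[keepM & keepA] * M[keepM & keepA]) /
             sum(w[keepM & keepA]))
  expected <- c(A = 1 / sqrt(fB), B = fB / sqrt(fB))  # recentred
  expect_equal(f$tmm_factor, unname(expected[f$sample]), tolerance = 1e-10)
})

test_that("TMM agrees with the edgeR reference implementation", {
  skip_if_not_installed("edgeR")
  set.seed(33)
  m <- matrix(rnbinom(400 * 6, mu = exp(runif(2400, 2, 7)), size = 5),
              400, 6, dimnames = list(paste0("g", 1:400), paste0("s", 1:6)))
  f <- compute_tmm_factors(m)
  expect_equal(f$tmm_factor, unname(edgeR::calcNormFactors(m, method = "TMM")),
               tolerance = 1e-10)
})

test_that("CPM scales by the effective library and stays finite in logs", {
  m <- matrix(c(100L, 50L), 1, 2, dimnames = list("g1", c("a", "b")))
  f <- tibble::tibble(sample = c("a", "b"), library_size = c(1e6, 1e6),
                      tmm_factor = c(1, 1), effective_library = c(1e6, 1e6))
  expect_equal(cpm(m, f)[1, "a"], 100)
  f2 <- f; f2$effective_library <- c(2e6, 2e6)
  expect_equal(cpm(m, f2)[1, "a"], 50)  # doubled factor halves CPM
  m0 <- matrix(c(0L, 10L), 1, 2, dimnames = list("g1", c("a", "b")))
  expect_true(all(is.finite(cpm(m0, f, log = TRUE))))
})

test_that("moment dispersion estimates recover the simulated truth", {
  set.seed(8)
  d <- toy_design(25, 25)
  mu <- exp(runif(2000, 3, 7))
  pois <- matrix(rpois(2000 * 50, mu), 2000, 50,
                 dimnames = list(paste0("g", 1:2000), d$sample_id))
  expect_lte(estimate_common_dispersion(pois, d), 0.02)

  nb <- matrix(rnbinom(2000 * 50, mu = mu, size = 5), 2000, 50,
               dimnames = dimnames(pois))
  phi <- estimate_common_dispersion(nb, d)
  expect_gt(phi, 0.15)
  expect_lt(phi, 0.25)

  const <- matrix(7L, 100, 50,
                  dimnames = list(paste0("g", 1:100), d$sample_id))
  expect_equal(estimate_common_dispersion(const, d), 0)
  expect_error(estimate_common_dispersion(pois[, 1:26], toy_design(25, 1)),
               "at least 2")
})

test_that("the conditional exact test degenerates to the binomial test", {
  d <- tibble::tibble(sample_id = c("a", "b"),
                      group = factor(c("early", "late"),
                                     levels = c("early", "late")))
  f <- tibble::tibble(sample = c("a", "b"), library_size = c(10, 10),
                      tmm_factor = c(1, 1), effective_library = c(10, 10))
  m <- matrix(c(3L, 7L), 1, 2, dimnames = list("g1", c("a", "b")))
  res <- exact_test(m, d, f, dispersion = 0)
  # conditional Poisson with equal libraries is Binomial(10, 1/2)
  expect_equal(res$PValue, 2 * pbinom(3, 10, 0.5), tolerance = 1e-12)
})

test_that("a symmetric gene gets log fold change 0 and p-value 1", {
  d <- toy_design(2, 2)
  m <- matrix(c(50L, 70L, 50L, 70L), 1, 4,
              dimnames = list("g1", d$sample_id))
  filler <- matrix(rep(c(100L, 80L, 100L, 80L), 5), 5, 4, byrow = TRUE,
                   dimnames = list(paste0("f", 1:5), d$sample_id))
  res <- exact_test(rbind(m, filler), d, factors = NULL, dispersion = 0.1)
  expect_equal(res$logFC[res$gene == "g1"], 0, tolerance = 1e-10)
  expect_equal(res$PValue[res$gene == "g1"], 1)
  expect_error(exact_test(m, d, NULL, dispersion = -0.1), "dispersion")
})

test_that("strong planted fold changes are recovered at small scale", {
  p <- sim_params(n_genes = 400, n_early = 10, n_late = 30,
                  de_fraction = 0.05, de_log2fc = 2, seed = 13)
  tr <- simulate_truth(p)
  d <- toy_design(10, 30)
  cts <- simulate_counts(tr, d, p)
  f <- compute_tmm_factors(cts)
  phi <- estimate_common_dispersion(cts, d, f)
  res <- exact_test(cts, d, f, phi)
  sens <- mean(res$FDR[res$gene %in% names(tr$de_genes)] < 0.05)
  expect_gt(sens, 0.8)
  # orientation: up-planted genes have positive logFC
  up <- names(tr$de_genes)[tr$de_genes > 0]
  expect_gt(mean(res$logFC[res$gene %in% up] > 0), 0.95)
})

test_that("BH adjustment follows the step-up construction", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  p_sorted <- sort(runif(50))
  expect_true(all(diff(bh_adjust(p_sorted)) >= 0))
  expect_true(all(bh_adjust(p_sorted) >= p_sorted))
  # permutation equivariance
  set.seed(3)
  p <- runif(30)
  perm <- sample(30)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})
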