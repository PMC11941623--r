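test_that("cohort assignment splits strictly below the age cutoff", {
  d <- assign_cohorts(c(69, 70, 55.5, 90), cutoff = 70)
  expect_equal(as.character(d$group), c("early", "late", "early", "late"))
  expect_equal(attr(d, "cutoff"), 70)
  expect_error(assign_cohorts(numeric(0)), "empty design")
  expect_error(assign_cohorts(c(60, -1)), "positive")
  expect_error(assign_cohorts(c(60, 61), sample_id = c("a", "a")),
               "duplicate")
})

test_that("simulated truth is deterministic and plants exact counts", {
  p <- sim_params(seed = 42)
  t1 <- simulate_truth(p)
  t2 <- simulate_truth(p)
  expect_identical(t1, t2)

  # 5 modules x 20 genes -> exactly 100 genes carry a module id
  expect_equal(sum(t1$module_of != "background"), 100)
  # de_fraction 0.05 of 2000 genes -> exactly 100 DE genes
  expect_equal(length(t1$de_genes), 100)
  # module 1 is planted as a coherently up-shifted perturbed set
  expect_equal(t1$perturbed_sets, "T1_M1")
  m1 <- names(t1$module_of)[t1$module_of == "M1"]
  expect_true(all(t1$de_genes[m1] == p$de_log2fc))
  # the remaining DE genes alternate signs deterministically
  rest <- setdiff(names(t1$de_genes), m1)
  expect_equal(sum(t1$de_genes[rest] > 0), sum(t1$de_genes[rest] < 0))

  expect_error(sim_params(n_genes = 50, n_modules = 10, module_size = 10),
               "exceed")
  expect_error(sim_params(de_fraction = 1.2), "de_fraction")
  expect_error(sim_params(dispersion = -1), "dispersion")
})

test_that("count simulation is reproducible and Poisson-calibrated", {
  p <- sim_params(n_genes = 100, n_early = 4, n_late = 6, seed = 3)
  tr <- simulate_truth(p)
  d <- toy_design(4, 6)
  expect_identical(simulate_counts(tr, d, p), simulate_counts(tr, d, p))

  # phi = 0, rho = 0, no DE, equal libraries: variance/mean ratio near 1
  p0 <- sim_params(n_genes = 5000, n_modules = 0, module_size = 1,
                   factor_loading = 0, dispersion = 0, de_fraction = 0,
                   n_true_terms = 0, n_early = 15, n_late = 15,
                   libsize_range = c(1e6, 1e6), seed = 7)
  tr0 <- simulate_truth(p0)
  cts <- simulate_counts(tr0, toy_design(15, 15), p0)
  ratio <- apply(cts, 1, var) / rowMeans(cts)
  expect_gt(mean(ratio, na.rm = TRUE), 0.9)
  expect_lt(mean(ratio, na.rm = TRUE), 1.1)
})

test_that("planted fold changes appear in group mean CPM ratios", {
  p <- sim_params(seed = 5)  # de_log2fc = 2 -> 4-fold
  tr <- simulate_truth(p)
  d <- toy_design(47, 174)
  cts <- simulate_counts(tr, d, p)
  # TMM-normalized CPM: planted fold changes shift the late group's
  # composition, which raw library-size CPM would absorb into every gene
  x <- cpm(cts, compute_tmm_factors(cts))
  # background DE genes carry only count noise; module genes add shared
  # latent-factor variation to the group means
  up <- names(tr$de_genes)[tr$de_genes > 0 &
                             tr$module_of[names(tr$de_genes)] == "background"]
  r <- rowMeans(x[up, d$group == "late"]) / rowMeans(x[up, d$group == "early"])
  expect_true(all(abs(r / 4 - 1) < 0.15))
})

test_that("annotation catalogue reproduces planted modules exactly", {
  p <- sim_params(n_genes = 300, n_early = 5, n_late = 5,
                  n_true_terms = 5, n_decoy_terms = 20, seed = 9)
  tr <- simulate_truth(p)
  gsc <- simulate_annotation(tr)
  expect_s3_class(gsc, "gene_set_collection")
  expect_length(gsc$sets, 25)
  for (k in 1:5) {
    mod <- names(tr$module_of)[tr$module_of == paste0("M", k)]
    term <- gsc$sets[[sprintf("T%d_M%d", k, k)]]
    jac <- length(intersect(mod, term)) / length(union(mod, term))
    expect_equal(jac, 1)
  }
  f <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gsc, f)
  back <- read_gmt(f)
  expect_identical(back$sets, gsc$sets)
  expect_identical(back$descriptions, gsc$descriptions)
})

test_that("intra-module pairs are more correlated than background pairs", {
  p <- sim_params(n_genes = 300, n_modules = 5, module_size = 20,
                  factor_loading = 0.5, de_fraction = 0, n_early = 0,
                  n_late = 120, seed = 21)
  tr <- simulate_truth(p)
  d <- assign_cohorts(seq(70, 95, length.out = 120))
  lc <- cpm(simulate_counts(tr, d, p), log = TRUE)
  cc <- abs(cor(t(lc)))
  same <- outer(tr$module_of, tr$module_of, `==`) &
    tr$module_of != "background"
  diag(same) <- NA
  bg <- outer(tr$module_of == "background", tr$module_of == "background",
              `&`)
  diag(bg) <- NA
  expect_gt(mean(cc[which(same)]), mean(cc[which(bg)]) + 0.2)
})

test_that("planted-partition graphs favour within-block edges", {
  g <- simulate_planted_partition(4, 25, 0.3, 0.01, seed = 2)
  expect_identical(g$edges, simulate_planted_partition(4, 25, 0.3, 0.01,
                                                       seed = 2)$edges)
  same <- g$membership[g$edges$from] == g$membership[g$edges$to]
  expect_gt(mean(same), 0.8)
})
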