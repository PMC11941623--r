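test_that("degree histograms count nodes by unit bins", {
  ring <- data.frame(from = c("a", "b", "c", "d"),
                     to = c("b", "c", "d", "a"))
  h <- degree_distribution(ring)
  expect_equal(h$degree, 2L)
  expect_equal(h$count, 4L)

  star <- data.frame(from = rep("c0", 3), to = paste0("l", 1:3))
  hs <- degree_distribution(star)
  expect_equal(hs$degree, c(1L, 3L))
  expect_equal(hs$count, c(3L, 1L))
  expect_equal(sum(hs$count), 4L)
})

test_that("identical histograms compare as exactly null", {
  h <- tibble::tibble(degree = c(1L, 2L, 3L), count = c(30L, 40L, 30L))
  cmp <- compare_degree_distributions(h, h)
  expect_equal(cmp$chi2, 0)
  expect_equal(cmp$cramers_v, 0)
  expect_equal(cmp$p, 1)
})

test_that("fully separated degree classes give chi2 = 2n and V = 1", {
  n <- 50L
  h1 <- tibble::tibble(degree = 1L, count = n)
  h2 <- tibble::tibble(degree = 2L, count = n)
  cmp <- compare_degree_distributions(h1, h2)
  expect_equal(cmp$chi2, 2 * n)
  expect_equal(cmp$cramers_v, 1)
})

test_that("the homogeneity test equals the Pearson formula", {
  h1 <- tibble::tibble(degree = c(1L, 2L), count = c(30L, 10L))
  h2 <- tibble::tibble(degree = c(1L, 2L), count = c(10L, 30L))
  cmp <- compare_degree_distributions(h1, h2)
  tab <- rbind(c(30, 10), c(10, 30))
  expect_equal(cmp$chi2, oracle_chi2(tab), tolerance = 1e-12)
  expect_equal(cmp$chi2, 20)
  expect_equal(cmp$cramers_v, sqrt(20 / 80), tolerance = 1e-12)
  expect_equal(cmp$df, 1L)
  expect_equal(cramers_v(tab), sqrt(oracle_chi2(tab) / 80),
               tolerance = 1e-12)
})

test_that("sparse tail bins are pooled before testing", {
  h1 <- tibble::tibble(degree = c(1L, 2L, 40L, 50L),
                       count = c(100L, 80L, 1L, 2L))
  h2 <- tibble::tibble(degree = c(1L, 2L, 45L), count = c(90L, 95L, 2L))
  cmp <- compare_degree_distributions(h1, h2)
  expect_lt(cmp$n_bins_used, 5L)
  expect_gte(cmp$n_bins_used, 2L)
  expect_true(is.finite(cmp$chi2) && cmp$p <= 1)
  expect_equal(cmp$n_total, as.integer(sum(h1$count) + sum(h2$count)))
})

test_that("network summaries report density, components and modules", {
  k5 <- as.data.frame(t(combn(letters[1:5], 2)))
  names(k5) <- c("from", "to")
  s <- summarize_network(k5)
  expect_equal(s$density, 1)
  expect_equal(s$n_components, 1)

  tri2 <- data.frame(from = c("a", "b", "c", "x", "y", "z"),
                     to = c("b", "c", "a", "y", "z", "x"))
  s2 <- summarize_network(tri2,
                          partition = tibble::tibble(node = c("a", "b", "c",
                                                              "x", "y", "z"),
                                                     module = rep(1:2, each = 3)))
  expect_equal(s2$component_sizes, c(3L, 3L))
  expect_equal(s2$n_modules, 2)
  expect_equal(s2$module_sizes, c(3L, 3L))

  empty <- structure(
    list(nodes = letters[1:4],
         edges = tibble::tibble(from = character(0), to = character(0),
                                weight = numeric(0), p_value = numeric(0)),
         threshold_value = 0, percentile = 99, n_samples = NULL,
         n_bins = NULL),
    class = "coexpression_network")
  s3 <- summarize_network(empty)
  expect_equal(s3$density, 0)
  expect_equal(s3$component_sizes, rep(1L, 4))
})
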