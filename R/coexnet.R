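#' Equal-frequency discretization of an expression matrix
#'
#' Rank-based assignment of each gene's values into `n_bins` bins of
#' near-equal occupancy (occupancies differ by at most 1 when values are
#' tie-free); ties are broken by stable input order. The default bin count
#' is `floor(sqrt(n_samples))`, the common choice for plug-in mutual
#' information estimation. A constant gene collapses into bin 1 (its MI with
#' anything is then 0).
#'
#' @param expr Numeric matrix, genes x samples.
#' @param n_bins Number of bins, at least 2 and at most the sample count.
#' @return A list of class `discretized_matrix`: `bins` (integer matrix with
#'   values in `1..n_bins`), `n_bins`, `scheme = "equal-frequency"`.
#' @examples
#' discretize_equal_frequency(matrix(1:4, 1, 4), n_bins = 2)$bins
#' @export
discretize_equal_frequency <- function(expr, n_bins = NULL) {
  stopifnot(is.matrix(expr), is.numeric(expr))
  n <- ncol(expr)
  if (is.null(n_bins)) n_bins <- max(2L, floor(sqrt(n)))
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) abort("n_bins must be at least 2")
  if (n < n_bins) abort("need at least as many samples as bins")
  bins <- t(apply(expr, 1, function(x) {
    if (max(x) == min(x)) return(rep(1L, n))
    r <- rank(x, ties.method = "first")
    as.integer(ceiling(r * n_bins / n))
  }))
  dimnames(bins) <- dimnames(expr)
  structure(list(bins = bins, n_bins = n_bins, scheme = "equal-frequency"),
            class = "discretized_matrix")
}

#' Plug-in mutual information of two discretized vectors, in bits
#'
#' Maximum-likelihood estimate
#' `I = sum_ij p_ij log2(p_ij / (p_i p_j))` from the joint contingency table
#' of two equal-length bin vectors. Always nonnegative (clamped at 0 against
#' rounding). The optional Miller-Madow correction adds
#' `(K_xy - K_x - K_y + 1) / (2 n ln 2)` bits, where the `K`s count occupied
#' cells.
#'
#' @param x_bins,y_bins Integer vectors of bin labels, equal length >= 2.
#' @param miller_madow Apply the Miller-Madow bias correction?
#' @return Mutual information in bits.
#' @examples
#' mutual_information(c(1, 1, 2, 2), c(1, 1, 2, 2))  # 1 bit
#' @export
mutual_information <- function(x_bins, y_bins, miller_madow = FALSE) {
  if (length(x_bins) != length(y_bins)) {
    abort("x_bins and y_bins must have equal length")
  }
  n <- length(x_bins)
  if (n < 2L) abort("need at least 2 observations")
  joint <- table(x_bins, y_bins)
  pj <- joint / n
  px <- rowSums(pj)
  py <- colSums(pj)
  nz <- pj > 0
  expected <- outer(px, py)
  mi <- sum(pj[nz] * log2(pj[nz] / expected[nz]))
  if (miller_madow) {
    mi <- mi + (sum(nz) - sum(px > 0) - sum(py > 0) + 1) / (2 * n * log(2))
  }
  max(mi, 0)
}

#' All pairwise mutual information values of a discretized matrix
#'
#' Computes the plug-in MI (bits) for every unordered gene pair; the
#' diagonal holds each gene's marginal entropy (its MI with itself).
#'
#' @param binned A [discretize_equal_frequency()] result.
#' @param miller_madow Apply the Miller-Madow bias correction?
#' @return A symmetric numeric genes x genes matrix of MI values in bits.
#' @export
pairwise_mi <- function(binned, miller_madow = FALSE) {
  stopifnot(inherits(binned, "discretized_matrix"))
  if (nrow(binned$bins) < 2L) abort("need at least 2 genes")
  m <- pairwise_mi_cpp(binned$bins - 1L, binned$n_bins, miller_madow)
  dimnames(m) <- list(rownames(binned$bins), rownames(binned$bins))
  m
}

#' Analytic significance of a mutual information value
#'
#' Uses the identity between mutual information and the likelihood-ratio G
#' statistic of independence, `G = 2 n ln(2) I_bits`, whose null
#' distribution on an `r x c` contingency table is chi-squared with
#' `(r - 1)(c - 1)` degrees of freedom. Returns the upper-tail probability;
#' monotone decreasing in both `mi` and `n`.
#'
#' @param mi Mutual information in bits (vectorized).
#' @param n Number of samples behind the estimate.
#' @param r,c Number of occupied bins for the two variables.
#' @return Upper-tail p-value(s).
#' @examples
#' mi_significance(0.0817, n = 100, r = 2, c = 2)
#' @export
mi_significance <- function(mi, n, r, c) {
  if (any(n <= 0)) abort("sample size must be positive")
  if (any(r < 2) || any(c < 2)) abort("need at least 2 bins per margin")
  if (any(mi < 0)) abort("mutual information must be nonnegative")
  g <- 2 * n * log(2) * mi
  pchisq(g, df = (r - 1) * (c - 1), lower.tail = FALSE)
}

#' Threshold pairwise MI values into a co-expression network
#'
#' Computes the stated percentile of all unordered-pair MI values (linear
#' interpolation between order statistics) and keeps edges with
#' `mi >= threshold` — inclusive, so the degenerate all-equal case keeps
#' every edge. Per-edge analytic p-values are recorded as provenance but not
#' used for filtering.
#'
#' @param mi_matrix Symmetric MI matrix from [pairwise_mi()].
#' @param percentile Percentile in `(0, 100)` of the pairwise MI
#'   distribution (default 99).
#' @param n_samples,n_bins Sample and bin counts behind the MI estimates,
#'   used for the analytic edge p-values; p-values are omitted when `NULL`.
#' @return A `coexpression_network`: list with `nodes` (all genes entering
#'   the comparison), `edges` (tibble `from`, `to`, `weight` in bits,
#'   `p_value`), `threshold_value`, `percentile`, `n_samples`, `n_bins`.
#' @export
threshold_at_percentile <- function(mi_matrix, percentile = 99,
                                    n_samples = NULL, n_bins = NULL) {
  stopifnot(is.matrix(mi_matrix), nrow(mi_matrix) == ncol(mi_matrix))
  if (percentile <= 0 || percentile >= 100) {
    abort("percentile must lie strictly between 0 and 100")
  }
  genes <- rownames(mi_matrix)
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(mi_matrix)))
  ut <- upper.tri(mi_matrix)
  vals <- mi_matrix[ut]
  if (length(vals) == 0L) abort("no gene pairs to threshold")
  thr <- unname(quantile(vals, probs = percentile / 100, type = 7))
  idx <- which(ut & mi_matrix >= thr, arr.ind = TRUE)
  edges <- tibble(
    from = genes[idx[, 1]],
    to = genes[idx[, 2]],
    weight = mi_matrix[idx]
  )
  edges <- edges[order(-edges$weight, edges$from, edges$to), ]
  edges$p_value <- if (!is.null(n_samples) && !is.null(n_bins)) {
    mi_significance(edges$weight, n_samples, n_bins, n_bins)
  } else {
    NA_real_
  }
  structure(
    list(nodes = genes, edges = edges, threshold_value = thr,
         percentile = percentile, n_samples = n_samples, n_bins = n_bins),
    class = "coexpression_network"
  )
}

#' Infer a mutual-information co-expression network from expression data
#'
#' Convenience wrapper chaining [discretize_equal_frequency()],
#' [pairwise_mi()] and [threshold_at_percentile()]: expression values
#' (typically log-CPM) are discretized into equal-frequency bins, all
#' pairwise plug-in MI values are computed, and the network keeps the pairs
#' above the stated percentile of the MI distribution.
#'
#' @param expr Numeric matrix, genes x samples (log-CPM recommended).
#' @param n_bins Bin count (default `floor(sqrt(n_samples))`).
#' @param percentile MI percentile retained (default 99).
#' @param miller_madow Apply the Miller-Madow bias correction?
#' @return A `coexpression_network`; see [threshold_at_percentile()].
#' @export
build_coexpression_network <- function(expr, n_bins = NULL, percentile = 99,
                                       miller_madow = FALSE) {
  binned <- discretize_equal_frequency(expr, n_bins)
  mi <- pairwise_mi(binned, miller_madow)
  threshold_at_percentile(mi, percentile,
                          n_samples = ncol(expr), n_bins = binned$n_bins)
}

#' @exportS3Method base::print
print.coexpression_network <- function(x, ...) {
  cat(sprintf(
    "<coexpression_network> %d nodes, %d edges (MI >= %.4g bits, %gth percentile)\n",
    length(x$nodes), nrow(x$edges), x$threshold_value, x$percentile))
  invisible(x)
}

#' @describeIn threshold_at_percentile Edge list as a tibble.
#' @param x A `coexpression_network`.
#' @param ... Unused.
#' @export
tidy.coexpression_network <- function(x, ...) {
  x$edges
}

#' @describeIn threshold_at_percentile One-row network summary.
#' @export
glance.coexpression_network <- function(x, ...) {
  deg <- node_degrees(x)
  tibble(
    n_nodes = length(x$nodes),
    n_connected_nodes = sum(deg > 0),
    n_edges = nrow(x$edges),
    threshold_value = x$threshold_value,
    percentile = x$percentile,
    n_samples = if (is.null(x$n_samples)) NA_integer_ else x$n_samples
  )
}

#' @describeIn threshold_at_percentile Degree-distribution plot of the
#'   thresholded network.
#' @param object A `coexpression_network`.
#' @export
autoplot.coexpression_network <- function(object, ...) {
  h <- degree_distribution(object)
  ggplot(as_tibble(h), aes(x = .data$degree, y = .data$count)) +
    geom_point() +
    scale_x_log10() +
    scale_y_log10() +
    labs(x = "node degree", y = "number of nodes") +
    theme_minimal()
}
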