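#' Remove genes with insufficient expression
#'
#' Keeps genes whose counts-per-million (computed on raw library sizes) reach
#' `min_cpm` in at least `min_samples` samples; gene order is preserved. The
#' conventional default for the two-cohort design is `min_cpm = 1` in at
#' least as many samples as the smaller cohort.
#'
#' @param counts Integer matrix, genes x samples.
#' @param min_cpm CPM threshold (inclusive).
#' @param min_samples Minimum number of samples reaching `min_cpm`
#'   (inclusive); must not exceed the number of samples.
#' @return The filtered count matrix. An empty result triggers a warning,
#'   not an error.
#' @examples
#' m <- matrix(c(0, 0, 50, 60, 5, 0), 3, 2, byrow = TRUE,
#'             dimnames = list(c("g1", "g2", "g3"), c("a", "b")))
#' filter_low_expression(m, min_cpm = 1, min_samples = 2)
#' @export
filter_low_expression <- function(counts, min_cpm = 1, min_samples = 1) {
  check_count_matrix(counts)
  if (min_samples > ncol(counts)) {
    abort("min_samples exceeds the number of samples")
  }
  lib <- colSums(counts)
  if (any(lib == 0)) abort("sample with zero library size")
  cpm_raw <- sweep(counts, 2, 1e6 / lib, `*`)
  keep <- rowSums(cpm_raw >= min_cpm) >= min_samples
  if (!any(keep)) warn("no genes survive the expression filter")
  counts[keep, , drop = FALSE]
}

check_count_matrix <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    abort("counts must be a numeric matrix (genes x samples)")
  }
  if (any(counts < 0)) abort("counts must be nonnegative")
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts))) {
    abort("counts must carry unique gene rownames")
  }
  invisible(TRUE)
}

#' Trimmed-mean-of-M-values normalization factors
#'
#' Computes one scaling factor per sample by the TMM method: against a
#' reference sample, per-gene log2 expression ratios (M values) are trimmed
#' by `trim_m` on M and `trim_a` on average log expression (A), and the
#' surviving M values are averaged with inverse-variance (binomial precision)
#' weights. The reference is the sample whose 75th-percentile CPM is closest
#' to the mean of those percentiles. Factors are recentred so their geometric
#' mean is 1; a sample's effective library is its raw library size times its
#' factor.
#'
#' @param counts Integer matrix, genes x samples, all library sizes positive.
#' @param trim_m Two-sided trim fraction on M values (default 0.30).
#' @param trim_a Two-sided trim fraction on A values (default 0.05).
#' @return A tibble with columns `sample`, `library_size`, `tmm_factor`,
#'   `effective_library`, carrying the reference sample id as the
#'   `"reference_sample"` attribute.
#' @examples
#' m <- matrix(rpois(200, 50), 20, 10,
#'             dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
#' compute_tmm_factors(m)
#' @export
compute_tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  check_count_matrix(counts)
  lib <- colSums(counts)
  if (any(lib <= 0)) abort("every sample needs a positive library size")

  # reference: 75th-percentile CPM closest to the mean of those percentiles
  q75 <- apply(sweep(counts, 2, 1e6 / lib, `*`), 2, quantile, probs = 0.75)
  ref <- which.min(abs(q75 - mean(q75)))

  f <- vapply(seq_len(ncol(counts)), function(k) {
    tmm_pair_factor(counts[, k], lib[k], counts[, ref], lib[ref],
                    trim_m, trim_a)
  }, numeric(1))
  f <- f / exp(mean(log(f)))

  out <- tibble(
    sample = colnames(counts),
    library_size = as.numeric(lib),
    tmm_factor = f,
    effective_library = as.numeric(lib) * f
  )
  attr(out, "reference_sample") <- colnames(counts)[ref]
  out
}

# one sample vs the reference; returns the (unrecentred) TMM factor
tmm_pair_factor <- function(y, n, yr, nr, trim_m, trim_a) {
  ok <- y > 0 & yr > 0
  if (!any(ok)) {
    warn("sample shares no positive genes with the reference; factor set to 1")
    return(1)
  }
  y <- y[ok]; yr <- yr[ok]
  m <- log2((y / n) / (yr / nr))
  a <- 0.5 * log2((y / n) * (yr / nr))
  w <- 1 / ((n - y) / (n * y) + (nr - yr) / (nr * yr))
  if (max(abs(m)) < 1e-6) return(1)

  ng <- length(m)
  lo_m <- floor(ng * trim_m) + 1
  hi_m <- ng + 1 - lo_m
  lo_a <- floor(ng * trim_a) + 1
  hi_a <- ng + 1 - lo_a
  rm_ <- rank(m); ra_ <- rank(a)
  keep <- rm_ >= lo_m & rm_ <= hi_m & ra_ >= lo_a & ra_ <= hi_a
  if (!any(keep)) return(1)
  2^(sum(w[keep] * m[keep]) / sum(w[keep]))
}

#' Counts per million on effective library sizes
#'
#' `CPM = 1e6 * count / effective_library`. With `log = TRUE`, returns
#' `log2(CPM + prior CPM)` where the prior CPM is `prior_count` reads on the
#' mean effective library, so zero counts map to a finite value.
#'
#' @param counts Integer matrix, genes x samples.
#' @param factors Normalization tibble from [compute_tmm_factors()]; when
#'   `NULL`, raw library sizes are used (factor 1).
#' @param log Return log2 CPM?
#' @param prior_count Pseudo-reads added (via the mean effective library)
#'   before taking logs.
#' @return Numeric matrix of (log-)CPM values with the same dimnames.
#' @export
cpm <- function(counts, factors = NULL, log = FALSE, prior_count = 0.5) {
  check_count_matrix(counts)
  eff <- effective_libs(counts, factors)
  if (any(eff <= 0)) abort("zero or negative effective library size")
  x <- sweep(counts, 2, 1e6 / eff, `*`)
  if (!log) return(x)
  log2(x + prior_count * 1e6 / mean(eff))
}

effective_libs <- function(counts, factors) {
  if (is.null(factors)) return(colSums(counts))
  stopifnot(all(c("sample", "effective_library") %in% names(factors)))
  if (!setequal(factors$sample, colnames(counts))) {
    abort("normalization factors do not match the samples in `counts`")
  }
  eff <- setNames(factors$effective_library, factors$sample)
  as.numeric(eff[colnames(counts)])
}

#' Method-of-moments common negative-binomial dispersion
#'
#' Estimates a single dispersion `phi` shared by all genes: counts are scaled
#' to a common effective library, group-centred, and the per-gene moment
#' estimate `(s^2 - mu) / mu^2` is averaged over genes (floored at 0). This
#' is a deliberately simple approximation to the shrinkage estimators of
#' dedicated DE tools, sufficient for the pipeline's comparative purpose.
#' Genes whose mean normalized count is below 1 are ignored as uninformative
#' for the moment ratio.
#'
#' @param counts Integer matrix, genes x samples.
#' @param design Cohort design tibble with `sample_id` and `group`; both
#'   groups need at least 2 samples.
#' @param factors Optional normalization tibble from [compute_tmm_factors()].
#' @return A single dispersion estimate `phi >= 0`.
#' @export
estimate_common_dispersion <- function(counts, design, factors = NULL) {
  check_count_matrix(counts)
  grp <- match_design(counts, design)
  if (any(table(grp) < 2L)) {
    abort("each group needs at least 2 samples to estimate dispersion")
  }
  eff <- effective_libs(counts, factors)
  z <- sweep(counts, 2, mean(eff) / eff, `*`)  # common-library scale
  mu_hat <- rowMeans(z)
  centred <- z
  for (g in levels(grp)) {
    idx <- which(grp == g)
    centred[, idx] <- z[, idx, drop = FALSE] -
      rowMeans(z[, idx, drop = FALSE])
  }
  s2 <- rowSums(centred^2) / (ncol(z) - nlevels(grp))
  use <- mu_hat >= 1
  if (!any(use)) return(0)
  phi <- mean((s2[use] - mu_hat[use]) / mu_hat[use]^2)
  max(phi, 0)
}

match_design <- function(counts, design) {
  stopifnot(all(c("sample_id", "group") %in% names(design)))
  idx <- match(colnames(counts), design$sample_id)
  if (any(is.na(idx))) abort("samples in counts missing from design")
  droplevels(factor(design$group[idx], levels = c("early", "late")))
}

#' Negative-binomial conditional exact test between two cohorts
#'
#' For each gene, counts are scaled to a common effective library, summed
#' within cohort, and the rounded group sums are compared by an exact
#' two-sided test conditional on their total: under dispersion `phi` the
#' early and late sums are negative binomial with sizes `n_early / phi` and
#' `n_late / phi` (Poisson when `phi = 0`), and the p-value is the
#' conditional probability of all outcomes as likely or less likely than the
#' one observed. Log2 fold changes are late over early on normalized group
#' means with a prior count of `prior_count` per group; false discovery
#' rates are Benjamini-Hochberg.
#'
#' @param counts Integer matrix, genes x samples.
#' @param design Cohort design tibble (`sample_id`, `group`); both groups
#'   must be nonempty.
#' @param factors Optional normalization tibble from [compute_tmm_factors()].
#' @param dispersion Common NB dispersion `phi >= 0`, e.g. from
#'   [estimate_common_dispersion()].
#' @param prior_count Offset (per group) used in the fold-change and
#'   log-CPM columns.
#' @return A tibble of class `dge_table` with columns `gene`, `logFC`
#'   (log2, late over early), `logCPM`, `PValue`, `FDR`; the orientation is
#'   recorded in the `"orientation"` attribute.
#' @export
exact_test <- function(counts, design, factors = NULL, dispersion = 0,
                       prior_count = 0.5) {
  check_count_matrix(counts)
  if (dispersion < 0) abort("dispersion must be >= 0")
  grp <- match_design(counts, design)
  if (nlevels(grp) < 2L) abort("exact test needs both cohorts present")
  eff <- effective_libs(counts, factors)
  common_lib <- exp(mean(log(eff)))
  z <- sweep(counts, 2, common_lib / eff, `*`)
  i1 <- which(grp == "early"); i2 <- which(grp == "late")
  n1 <- length(i1); n2 <- length(i2)
  s1 <- round(rowSums(z[, i1, drop = FALSE]))
  s2 <- round(rowSums(z[, i2, drop = FALSE]))

  p <- vapply(seq_along(s1), function(g) {
    nb_exact_pvalue(s1[g], s2[g], n1, n2, dispersion)
  }, numeric(1))

  logfc <- log2((s2 / n2 + prior_count) / (s1 / n1 + prior_count))
  logcpm <- log2(1e6 * ((s1 + s2 + 2 * prior_count) / (n1 + n2)) / common_lib)

  out <- tibble(
    gene = rownames(counts),
    logFC = unname(logfc),
    logCPM = unname(logcpm),
    PValue = unname(p),
    FDR = bh_adjust(unname(p))
  )
  class(out) <- c("dge_table", class(out))
  attr(out, "orientation") <- "late_over_early"
  attr(out, "dispersion") <- dispersion
  out
}

# two-sided conditional exact NB p-value for group sums s1 (n1 samples)
# and s2 (n2 samples) under common per-sample mean and dispersion phi
nb_exact_pvalue <- function(s1, s2, n1, n2, phi) {
  t <- s1 + s2
  if (t == 0) return(1)
  m <- t / (n1 + n2)
  mu1 <- n1 * m; mu2 <- n2 * m
  if (phi > 0) {
    size1 <- n1 / phi; size2 <- n2 / phi
    lo1 <- qnbinom(1e-13, size = size1, mu = mu1)
    hi1 <- qnbinom(1e-13, size = size1, mu = mu1, lower.tail = FALSE)
    lo2 <- qnbinom(1e-13, size = size2, mu = mu2)
    hi2 <- qnbinom(1e-13, size = size2, mu = mu2, lower.tail = FALSE)
    ld1 <- function(a) dnbinom(a, size = size1, mu = mu1, log = TRUE)
    ld2 <- function(a) dnbinom(a, size = size2, mu = mu2, log = TRUE)
  } else {
    lo1 <- qpois(1e-13, mu1); hi1 <- qpois(1e-13, mu1, lower.tail = FALSE)
    lo2 <- qpois(1e-13, mu2); hi2 <- qpois(1e-13, mu2, lower.tail = FALSE)
    ld1 <- function(a) dpois(a, mu1, log = TRUE)
    ld2 <- function(a) dpois(a, mu2, log = TRUE)
  }
  lo <- max(0, lo1, t - hi2)
  hi <- min(t, hi1, t - lo2)
  if (lo > hi) { lo <- 0; hi <- t }   # degenerate window: fall back to full support
  lo <- min(lo, s1)
  hi <- max(hi, s1)
  a <- lo:hi
  logf <- ld1(a) + ld2(t - a)
  log_obs <- ld1(s1) + ld2(s2)
  mx <- max(logf)
  f <- exp(logf - mx)
  keep <- logf <= log_obs + 1e-8
  min(1, sum(f[keep]) / sum(f))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts p-values to false discovery rates by the step-up rule
#' `q_(i) = min_{j >= i} m p_(j) / j`, capped at 1 and returned in input
#' order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted probabilities of the same length.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' @describeIn exact_test Volcano plot (log2 fold change versus -log10 FDR).
#' @param object,x A `dge_table`.
#' @param fdr_threshold Significance line drawn on the volcano plot and used
#'   to colour genes.
#' @param ... Unused.
#' @export
autoplot.dge_table <- function(object, fdr_threshold = 0.05, ...) {
  df <- as_tibble(object)
  df$significant <- df$FDR < fdr_threshold
  ggplot(df, aes(x = .data$logFC, y = -log10(pmax(.data$FDR, 1e-300)),
                 colour = .data$significant)) +
    geom_point(size = 0.6, alpha = 0.7) +
    scale_colour_manual(values = c(`FALSE` = "darkgreen", `TRUE` = "blue")) +
    geom_hline(yintercept = -log10(fdr_threshold), linetype = "dashed") +
    labs(x = "log2 fold change (late / early)", y = "-log10 FDR",
         colour = sprintf("FDR < %g", fdr_threshold)) +
    theme_minimal()
}

#' @describeIn exact_test One-row summary of a DE run.
#' @export
glance.dge_table <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_fdr_05 = sum(x$FDR < 0.05),
    dispersion = attr(x, "dispersion"),
    orientation = attr(x, "orientation")
  )
}
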