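#' Per-gene log2 fold changes between cohorts
#'
#' Difference of group means on the log2 expression scale (late minus early
#' by default), the input statistic for gene-set perturbation scoring.
#'
#' @param log_expr Numeric matrix of log2-scale expression, genes x samples.
#' @param design Cohort design tibble (`sample_id`, `group`); both groups
#'   must be nonempty.
#' @param test_group Group whose mean is taken first (default `"late"`,
#'   matching the DE fold-change orientation).
#' @return Named numeric vector of per-gene fold changes (log2 units).
#' @export
gene_fold_changes <- function(log_expr, design, test_group = "late") {
  stopifnot(is.matrix(log_expr), is.numeric(log_expr))
  grp <- match_design(log_expr, design)
  if (nlevels(grp) < 2L) abort("both cohorts must have at least one sample")
  ref_group <- setdiff(levels(grp), test_group)
  m_test <- rowMeans(log_expr[, grp == test_group, drop = FALSE])
  m_ref <- rowMeans(log_expr[, grp == ref_group, drop = FALSE])
  m_test - m_ref
}

#' Gene-set perturbation test against the all-gene background
#'
#' Tests whether a gene set's fold changes are shifted relative to the
#' background of all measured genes with a two-sample Welch t statistic
#' `t = (mean_set - mean_bg) / sqrt(s_set^2 / m + s_bg^2 / n)`, reporting
#' separate upper- (`p_up`) and lower-tail (`p_down`) probabilities so that
#' coordinated up- and down-regulation inside one pathway are both
#' detectable. By default the background includes the set itself (the
#' convention of the generally applicable set-enrichment approach);
#' `exclusive_background = TRUE` removes it.
#'
#' @param fold_changes Named numeric vector of per-gene fold changes, e.g.
#'   from [gene_fold_changes()].
#' @param set Character vector of gene ids; at least 2 must be measured.
#' @param exclusive_background Exclude the set from the background?
#' @return A one-row tibble: `set_size_used`, `t_stat`, `df`, `p_up`,
#'   `p_down`.
#' @export
gage_set_test <- function(fold_changes, set, exclusive_background = FALSE) {
  stopifnot(is.numeric(fold_changes), !is.null(names(fold_changes)))
  in_set <- names(fold_changes) %in% set
  m <- sum(in_set)
  if (m < 2L) abort("fewer than 2 set genes are measured")
  fs <- fold_changes[in_set]
  fb <- if (exclusive_background) fold_changes[!in_set] else fold_changes
  n <- length(fb)
  v_s <- var(fs) / m
  v_b <- var(fb) / n
  t_stat <- (mean(fs) - mean(fb)) / sqrt(v_s + v_b)
  df <- (v_s + v_b)^2 /
    (v_s^2 / (m - 1) + v_b^2 / (n - 1))
  tibble(
    set_size_used = m,
    t_stat = t_stat,
    df = df,
    p_up = pt(t_stat, df, lower.tail = FALSE),
    p_down = pt(t_stat, df)
  )
}

#' Run the set-perturbation test over a catalogue
#'
#' Applies [gage_set_test()] to every term of a catalogue and adjusts each
#' direction separately by Benjamini-Hochberg. Terms with fewer than 2
#' measured genes are skipped and recorded with `NA` statistics.
#'
#' @inheritParams gage_set_test
#' @param gsc A [gene_set_collection()].
#' @return A tibble of class `gage_result` with one row per term: `term`,
#'   `set_size_used`, `t_stat`, `df`, `p_up`, `p_down`, `q_up`, `q_down`.
#' @export
run_gage <- function(fold_changes, gsc, exclusive_background = FALSE) {
  stopifnot(inherits(gsc, "gene_set_collection"))
  rows <- lapply(names(gsc$sets), function(id) {
    usable <- sum(names(fold_changes) %in% gsc$sets[[id]])
    if (usable < 2L) {
      return(tibble(term = id, set_size_used = usable, t_stat = NA_real_,
                    df = NA_real_, p_up = NA_real_, p_down = NA_real_))
    }
    cbind(tibble(term = id),
          gage_set_test(fold_changes, gsc$sets[[id]], exclusive_background))
  })
  out <- as_tibble(do.call(rbind, rows))
  tested <- !is.na(out$p_up)
  out$q_up <- out$q_down <- NA_real_
  out$q_up[tested] <- bh_adjust(out$p_up[tested])
  out$q_down[tested] <- bh_adjust(out$p_down[tested])
  class(out) <- c("gage_result", class(out))
  out
}

#' Paired-column set-perturbation test with Stouffer combination
#'
#' Alternative scheme in which every test-cohort column is compared against
#' every reference-cohort column: per pair, fold changes are the column
#' difference and each set is scored with [gage_set_test()]; per-pair one
#' sided p-values are combined across pairs by Stouffer's method.
#'
#' @param log_expr Numeric matrix of log2-scale expression.
#' @param design Cohort design tibble.
#' @param gsc A [gene_set_collection()].
#' @param test_group Cohort treated as the test condition (default
#'   `"late"`).
#' @param max_pairs Cap on the number of column pairs scored (pairs are
#'   taken in deterministic column order); keeps the quadratic pairing
#'   affordable on large designs.
#' @return A tibble with one row per term: `term`, `set_size_used`,
#'   `n_pairs`, `p_up`, `p_down`, `q_up`, `q_down`.
#' @export
run_gage_paired <- function(log_expr, design, gsc, test_group = "late",
                            max_pairs = 200L) {
  grp <- match_design(log_expr, design)
  ref_group <- setdiff(levels(grp), test_group)
  it <- which(grp == test_group)
  ir <- which(grp == ref_group)
  pairs <- expand.grid(test = it, ref = ir)
  pairs <- pairs[seq_len(min(nrow(pairs), max_pairs)), , drop = FALSE]

  z_up <- z_down <- matrix(NA_real_, length(gsc$sets), nrow(pairs),
                           dimnames = list(names(gsc$sets), NULL))
  sizes <- setNames(integer(length(gsc$sets)), names(gsc$sets))
  for (p_i in seq_len(nrow(pairs))) {
    fc <- log_expr[, pairs$test[p_i]] - log_expr[, pairs$ref[p_i]]
    for (id in names(gsc$sets)) {
      usable <- sum(names(fc) %in% gsc$sets[[id]])
      sizes[id] <- usable
      if (usable < 2L) next
      r <- gage_set_test(fc, gsc$sets[[id]])
      z_up[id, p_i] <- stats::qnorm(r$p_up, lower.tail = FALSE)
      z_down[id, p_i] <- stats::qnorm(r$p_down, lower.tail = FALSE)
    }
  }
  stouffer <- function(z) {
    ok <- !is.na(z)
    if (!any(ok)) return(NA_real_)
    stats::pnorm(sum(z[ok]) / sqrt(sum(ok)), lower.tail = FALSE)
  }
  out <- tibble(
    term = names(gsc$sets),
    set_size_used = as.integer(sizes),
    n_pairs = nrow(pairs),
    p_up = apply(z_up, 1, stouffer),
    p_down = apply(z_down, 1, stouffer)
  )
  tested <- !is.na(out$p_up)
  out$q_up <- out$q_down <- NA_real_
  out$q_up[tested] <- bh_adjust(out$p_up[tested])
  out$q_down[tested] <- bh_adjust(out$p_down[tested])
  out
}
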