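#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`:
#' the chance of drawing at least `k` annotated genes when `n` genes are
#' drawn without replacement from a universe of `N` genes of which `K`
#' carry the annotation. Vectorized over all arguments.
#'
#' @param k Observed overlap (successes drawn).
#' @param K Annotated genes in the universe.
#' @param n Genes drawn (module size in the universe).
#' @param N Universe size.
#' @return Upper-tail probability `P(X >= k)`.
#' @examples
#' hypergeometric_pvalue(5, 5, 5, 20)  # 1 / choose(20, 5)
#' @export
hypergeometric_pvalue <- function(k, K, n, N) {
  args <- cbind(k, K, n, N)
  k <- args[, 1]; K <- args[, 2]; n <- args[, 3]; N <- args[, 4]
  if (any(k < 0) || any(K < 0) || any(n < 0) || any(N < 0)) {
    abort("counts must be nonnegative")
  }
  if (any(K > N) || any(n > N)) abort("K and n must not exceed N")
  if (any(k > pmin(K, n))) abort("overlap k cannot exceed min(K, n)")
  unname(phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE))
}

#' Hypergeometric over-representation of modules against a catalogue
#'
#' Tests every (module, term) pair for over-representation of the term's
#' genes inside the module, within a stated gene universe: catalogue sets
#' are intersected with the universe, modules smaller than
#' `min_module_size` (within the universe) are dropped, and one
#' Benjamini-Hochberg family is formed jointly over all tested pairs
#' (`per_module = TRUE` instead adjusts within each module).
#'
#' @param partition A [mapeq_partition] (or `node`/`module` data frame).
#' @param catalogue A [gene_set_collection()].
#' @param universe Character vector of gene ids forming the testing
#'   universe, typically the genes of the analyzed network.
#' @param min_module_size Smallest module (within the universe) tested.
#' @param per_module Adjust p-values within each module instead of jointly?
#' @return A tibble of class `enrichment_table` with columns `module`,
#'   `term`, `k` (overlap), `n` (module size in universe), `K` (term size in
#'   universe), `N` (universe size), `p`, `q`.
#' @export
enrich_modules <- function(partition, catalogue, universe,
                           min_module_size = 10, per_module = FALSE) {
  stopifnot(inherits(catalogue, "gene_set_collection"))
  df <- if (inherits(partition, "mapeq_partition")) tidy(partition) else
    as_tibble(partition)
  stopifnot(all(c("node", "module") %in% names(df)))
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) abort("empty gene universe")
  N <- length(universe)

  df <- df[df$node %in% universe, , drop = FALSE]
  skipped <- setdiff(unique(partition$module), unique(df$module))
  if (length(skipped) > 0L) {
    warn(sprintf("%d module(s) disjoint from the universe were skipped",
                 length(skipped)))
  }
  module_genes <- split(df$node, df$module)
  module_genes <- module_genes[lengths(module_genes) >= min_module_size]
  sets <- lapply(catalogue$sets, intersect, y = universe)
  sets <- sets[lengths(sets) > 0L]
  if (length(module_genes) == 0L || length(sets) == 0L) {
    out <- tibble(module = character(0), term = character(0),
                  k = integer(0), n = integer(0), K = integer(0),
                  N = integer(0), p = numeric(0), q = numeric(0))
    class(out) <- c("enrichment_table", class(out))
    return(out)
  }

  grid <- expand.grid(module = names(module_genes), term = names(sets),
                      stringsAsFactors = FALSE)
  n_vec <- lengths(module_genes)[grid$module]
  K_vec <- lengths(sets)[grid$term]
  k_vec <- mapply(function(m, t) {
    length(intersect(module_genes[[m]], sets[[t]]))
  }, grid$module, grid$term)
  p <- hypergeometric_pvalue(k_vec, K_vec, n_vec, N)
  out <- tibble(
    module = grid$module, term = grid$term,
    k = as.integer(k_vec), n = as.integer(n_vec),
    K = as.integer(K_vec), N = as.integer(N),
    p = as.numeric(p)
  )
  out$q <- if (per_module) {
    stats::ave(out$p, out$module, FUN = bh_adjust)
  } else {
    bh_adjust(out$p)
  }
  out <- out[order(out$q, out$p, out$module, out$term), ]
  class(out) <- c("enrichment_table", class(out))
  out
}

#' Bipartite module-function network from an enrichment table
#'
#' Two-layer graph linking co-expression modules to the functional terms
#' they are significantly enriched for: nodes are modules with at least one
#' significant term plus terms with at least one significant module, and
#' edges are exactly the enrichment rows with `q < q_threshold`.
#'
#' @param enrichment An [enrich_modules()] table.
#' @param q_threshold BH-adjusted significance threshold (default 0.05).
#' @return A `bipartite_network`: list with `module_nodes`, `term_nodes`
#'   and `edges` (tibble `module`, `term`, `q`).
#' @export
build_bipartite <- function(enrichment, q_threshold = 0.05) {
  stopifnot(all(c("module", "term", "q") %in% names(enrichment)))
  sig <- enrichment[!is.na(enrichment$q) & enrichment$q < q_threshold, ]
  structure(
    list(
      module_nodes = unique(sig$module),
      term_nodes = unique(sig$term),
      edges = tibble(module = sig$module, term = sig$term, q = sig$q),
      q_threshold = q_threshold
    ),
    class = "bipartite_network"
  )
}

#' @exportS3Method base::print
print.bipartite_network <- function(x, ...) {
  cat(sprintf(
    "<bipartite_network> %d modules, %d terms, %d enrichment edges (q < %g)\n",
    length(x$module_nodes), length(x$term_nodes), nrow(x$edges),
    x$q_threshold))
  invisible(x)
}

#' @describeIn build_bipartite Edge list as a tibble.
#' @param x A `bipartite_network`.
#' @param ... Unused.
#' @export
tidy.bipartite_network <- function(x, ...) {
  x$edges
}

#' @describeIn build_bipartite One-row summary, including the count of
#'   distinct enriched functional terms.
#' @export
glance.bipartite_network <- function(x, ...) {
  tibble(
    n_modules = length(x$module_nodes),
    n_terms = length(x$term_nodes),
    n_edges = nrow(x$edges),
    q_threshold = x$q_threshold
  )
}
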