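# Independent oracles used to check the package's implementations.
# Deliberately written as plain loops over the defining formulas, sharing no
# code with the package internals.

# two-level map-equation description length, straight from the definition
oracle_map_L <- function(edges, memb) {
  w2 <- 2 * sum(edges$weight)
  nodes <- names(memb)
  p <- setNames(rep(0, length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    p[[edges$from[i]]] <- p[[edges$from[i]]] + edges$weight[i] / w2
    p[[edges$to[i]]] <- p[[edges$to[i]]] + edges$weight[i] / w2
  }
  mods <- unique(as.character(memb))
  q <- setNames(rep(0, length(mods)), mods)
  for (i in seq_len(nrow(edges))) {
    ma <- as.character(memb[[edges$from[i]]])
    mb <- as.character(memb[[edges$to[i]]])
    if (ma != mb) {
      q[[ma]] <- q[[ma]] + edges$weight[i] / w2
      q[[mb]] <- q[[mb]] + edges$weight[i] / w2
    }
  }
  ent <- function(v) {
    v <- v[v > 0]
    if (length(v) == 0) return(0)
    v <- v / sum(v)
    -sum(v * log2(v))
  }
  L <- if (sum(q) > 0) sum(q) * ent(q) else 0
  for (m in mods) {
    pm <- p[as.character(memb[nodes]) == m]
    L <- L + (q[[m]] + sum(pm)) * ent(c(q[[m]], pm))
  }
  L
}

# all set partitions of n items as restricted growth strings
all_partitions <- function(n) {
  res <- list()
  rec <- function(a, mx) {
    i <- length(a) + 1L
    if (i > n) {
      res[[length(res) + 1L]] <<- a
      return(invisible())
    }
    for (v in seq_len(mx + 1L)) rec(c(a, v), max(mx, v))
  }
  rec(integer(0), 0L)
  res
}

# random undirected weighted graph on n nodes with at least one edge
random_small_graph <- function(n, p_edge = 0.45) {
  repeat {
    adj <- matrix(runif(n * n) < p_edge, n, n)
    adj[lower.tri(adj, diag = TRUE)] <- FALSE
    idx <- which(adj, arr.ind = TRUE)
    if (nrow(idx) >= 1) break
  }
  nodes <- letters[seq_len(n)]
  data.frame(from = nodes[idx[, 1]], to = nodes[idx[, 2]],
             weight = round(runif(nrow(idx), 0.5, 2), 2))
}

# hypergeometric upper tail by explicit pmf summation over binomial
# coefficients (exact in double precision for N <= 30)
oracle_hyper_tail <- function(k, K, n, N) {
  x <- k:min(K, n)
  sum(choose(K, x) * choose(N - K, n - x)) / choose(N, n)
}

# Pearson chi-squared from the textbook formula
oracle_chi2 <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# small two-cohort design with deterministic ages
toy_design <- function(n_early, n_late) {
  ages <- c(seq(55, 69, length.out = n_early),
            seq(70, 92, length.out = n_late))
  assign_cohorts(ages)
}
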