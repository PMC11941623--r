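# normalize the various network representations to an edge tibble
# (from, to, weight) plus the node universe
net_edges <- function(network) {
  if (inherits(network, "coexpression_network")) {
    return(list(edges = network$edges[, c("from", "to", "weight")],
                nodes = network$nodes))
  }
  if (igraph::is_igraph(network)) {
    df <- igraph::as_data_frame(network, what = "edges")
    w <- if ("weight" %in% names(df)) df$weight else rep(1, nrow(df))
    return(list(edges = tibble(from = as.character(df$from),
                               to = as.character(df$to), weight = w),
                nodes = igraph::V(network)$name))
  }
  if (is.data.frame(network)) {
    stopifnot(all(c("from", "to") %in% names(network)))
    w <- if ("weight" %in% names(network)) network$weight else
      rep(1, nrow(network))
    edges <- tibble(from = as.character(network$from),
                    to = as.character(network$to), weight = as.numeric(w))
    return(list(edges = edges, nodes = unique(c(edges$from, edges$to))))
  }
  abort("unsupported network representation")
}

#' Stationary visit rates of the map-equation random walk
#'
#' For an undirected weighted graph the random walk's stationary
#' distribution is closed-form: `p_alpha = strength(alpha) / (2 W)` with `W`
#' the total edge weight. Rates sum to 1 over connected nodes; isolated
#' nodes get rate 0 with a warning.
#'
#' @param network A `coexpression_network`, igraph graph, or edge data frame
#'   with columns `from`, `to` and optional `weight`; must carry at least
#'   one edge.
#' @return Named numeric vector of visit rates over the network's nodes.
#' @examples
#' ring <- data.frame(from = c("a", "b", "c", "d"),
#'                    to = c("b", "c", "d", "a"))
#' visit_rates(ring)
#' @export
visit_rates <- function(network) {
  net <- net_edges(network)
  if (nrow(net$edges) == 0L) abort("network has no edges")
  if (any(net$edges$weight <= 0)) abort("edge weights must be positive")
  if (any(net$edges$from == net$edges$to)) abort("self-loops are not allowed")
  w2 <- 2 * sum(net$edges$weight)
  strength <- setNames(numeric(length(net$nodes)), net$nodes)
  for (col in c("from", "to")) {
    s <- tapply(net$edges$weight, net$edges[[col]], sum)
    strength[names(s)] <- strength[names(s)] + s
  }
  if (any(strength == 0)) {
    warn(sprintf("%d isolated node(s) receive visit rate 0",
                 sum(strength == 0)))
  }
  strength / w2
}

#' Evaluate the two-level map equation for a partition
#'
#' Description length (bits per random-walk step) of a two-level modular
#' code: `L = q H(Q) + sum_i p_i H(P^i)`, with `q_i` the normalized weight
#' of edges leaving module i, `q = sum_i q_i`, `H(Q)` the entropy of the
#' module-exit distribution, `p_i = q_i + sum_{alpha in i} p_alpha` and
#' `H(P^i)` the entropy of module i's within-module codebook (its exit plus
#' its nodes' visit rates).
#'
#' @param network A network accepted by [visit_rates()].
#' @param module_of Named vector mapping every connected node to a module
#'   id, or a [mapeq_partition] object.
#' @return A list of class `map_score`: `total`, `index_term`,
#'   `module_terms` (named, bits per module), `visit_rates`, `exit_rates`.
#' @examples
#' ring <- data.frame(from = c("a", "b", "c", "d"),
#'                    to = c("b", "c", "d", "a"))
#' map_equation_length(ring, c(a = 1, b = 1, c = 1, d = 1))$total  # 2 bits
#' @export
map_equation_length <- function(network, module_of) {
  net <- net_edges(network)
  if (inherits(module_of, "mapeq_partition")) {
    module_of <- setNames(module_of$module, module_of$node)
  }
  p <- visit_rates(network)
  p <- p[p > 0]
  missing <- setdiff(names(p), names(module_of))
  if (length(missing) > 0L) {
    abort(sprintf("%d node(s) missing from the partition, e.g. %s",
                  length(missing), missing[1]))
  }
  mods <- as.character(module_of[names(p)])
  mod_ids <- sort(unique(mods))

  w2 <- 2 * sum(net$edges$weight)
  cross <- module_of[net$edges$from] != module_of[net$edges$to]
  q <- setNames(numeric(length(mod_ids)), mod_ids)
  if (any(cross)) {
    for (col in c("from", "to")) {
      m <- as.character(module_of[net$edges[[col]][cross]])
      s <- tapply(net$edges$weight[cross] / w2, m, sum)
      q[names(s)] <- q[names(s)] + s
    }
  }
  s_mod <- tapply(p, mods, sum)[mod_ids]
  q_tot <- sum(q)

  plogp <- function(x) ifelse(x > 0, x * log2(x), 0)
  entropy <- function(x) {
    x <- x[x > 0]
    if (length(x) == 0L) return(0)
    -sum(plogp(x / sum(x)))
  }
  index_term <- q_tot * entropy(q)
  module_terms <- vapply(mod_ids, function(m) {
    p_i <- q[m] + s_mod[m]
    p_i * entropy(c(q[m], p[mods == m]))
  }, numeric(1))
  structure(
    list(total = index_term + sum(module_terms),
         index_term = index_term,
         module_terms = module_terms,
         visit_rates = p,
         exit_rates = q),
    class = "map_score"
  )
}

#' Minimize the map equation by multi-trial greedy search
#'
#' Louvain-style optimization of the two-level map equation: each trial
#' shuffles the node order, repeatedly moves single nodes to the neighboring
#' (or a fresh) module when that lowers the description length, aggregates
#' modules into supernodes and repeats, finishing with a node-level
#' refinement pass; the best partition over `n_trials` independent trials is
#' returned. Deterministic given `(seed, n_trials)`. Ties in greedy moves go
#' to the lowest module id. Isolated nodes are dropped before optimization
#' (`keep_isolated = TRUE` instead assigns each its own module).
#'
#' @param network A network accepted by [visit_rates()].
#' @param n_trials Number of independent optimization trials (default 1000).
#' @param seed Integer seed for the trial node orders.
#' @param keep_isolated Give isolated nodes singleton modules instead of
#'   dropping them?
#' @return A `mapeq_partition`: tibble with columns `node` and `module`
#'   (contiguous integers from 1), with attributes `description_length`
#'   (bits), `n_modules`, `n_trials` and `seed`.
#' @examples
#' tri2 <- data.frame(from = c("a", "b", "c", "x", "y", "z"),
#'                    to = c("b", "c", "a", "y", "z", "x"))
#' optimize_partition(tri2, n_trials = 10, seed = 1)
#' @export
optimize_partition <- function(network, n_trials = 1000, seed = 1L,
                               keep_isolated = FALSE) {
  net <- net_edges(network)
  nodes <- net$nodes
  if (length(nodes) == 0L) abort("network has no nodes")

  if (nrow(net$edges) == 0L) {
    # no flow at all: every node is its own (degenerate) module, L = 0
    out <- tibble(node = nodes, module = seq_along(nodes))
    return(new_mapeq_partition(out, 0, n_trials, seed))
  }

  deg_nodes <- unique(c(net$edges$from, net$edges$to))
  isolated <- setdiff(nodes, deg_nodes)
  idx_from <- match(net$edges$from, deg_nodes) - 1L
  idx_to <- match(net$edges$to, deg_nodes) - 1L

  res <- optimize_partition_cpp(length(deg_nodes), idx_from, idx_to,
                                net$edges$weight, as.integer(n_trials),
                                as.integer(seed))
  module <- res$membership + 1L
  out <- tibble(node = deg_nodes, module = as.integer(module))
  if (keep_isolated && length(isolated) > 0L) {
    out <- rbind(out, tibble(node = isolated,
                             module = max(module) + seq_along(isolated)))
  }
  new_mapeq_partition(out, res$codelength, n_trials, seed)
}

new_mapeq_partition <- function(df, codelength, n_trials, seed) {
  stopifnot(all(c("node", "module") %in% names(df)))
  df <- as_tibble(df)
  class(df) <- c("mapeq_partition", class(df))
  attr(df, "description_length") <- codelength
  attr(df, "n_modules") <- length(unique(df$module))
  attr(df, "n_trials") <- n_trials
  attr(df, "seed") <- seed
  df
}

#' @describeIn optimize_partition Node-to-module table as a plain tibble.
#' @param x A `mapeq_partition`.
#' @param ... Unused.
#' @export
tidy.mapeq_partition <- function(x, ...) {
  tibble(node = x$node, module = x$module)
}

#' @describeIn optimize_partition One-row summary: module count, description
#'   length, largest-module size.
#' @export
glance.mapeq_partition <- function(x, ...) {
  sizes <- table(x$module)
  tibble(
    n_modules = attr(x, "n_modules"),
    description_length = attr(x, "description_length"),
    n_nodes = nrow(x),
    max_module_size = as.integer(max(sizes)),
    median_module_size = as.numeric(median(sizes))
  )
}

#' @describeIn optimize_partition Module-size histogram.
#' @param object A `mapeq_partition`.
#' @export
autoplot.mapeq_partition <- function(object, ...) {
  sizes <- as.integer(table(object$module))
  ggplot(tibble(size = sizes), aes(x = .data$size)) +
    geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    labs(x = "module size (genes)", y = "number of modules") +
    theme_minimal()
}
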