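node_degrees <- function(network) {
  net <- net_edges(network)
  deg <- setNames(integer(length(net$nodes)), net$nodes)
  tab <- table(c(net$edges$from, net$edges$to))
  deg[names(tab)] <- as.integer(tab)
  deg
}

#' Degree histogram of a thresholded network
#'
#' Histogram of unweighted node degrees over unit integer bins. By default
#' only nodes that carry at least one edge are counted (the nodes of the
#' drawn network); `include_isolated = TRUE` adds a degree-0 bin for the
#' remaining genes of the node universe.
#'
#' @param network A network accepted by [visit_rates()].
#' @param include_isolated Count degree-0 nodes of the node universe?
#' @return A tibble of class `degree_histogram` with columns `degree` and
#'   `count`; `sum(count)` equals the number of counted nodes (stored in
#'   attribute `n_nodes`, with the binning scheme in attribute `scheme`).
#' @export
degree_distribution <- function(network, include_isolated = FALSE) {
  deg <- node_degrees(network)
  if (length(deg) == 0L) abort("network has no nodes")
  if (!include_isolated) deg <- deg[deg > 0]
  tab <- table(factor(deg, levels = sort(unique(deg))))
  out <- tibble(degree = as.integer(names(tab)), count = as.integer(tab))
  class(out) <- c("degree_histogram", class(out))
  attr(out, "n_nodes") <- sum(out$count)
  attr(out, "scheme") <- "unit integer bins"
  out
}

#' Compare two degree distributions by chi-squared and Cramer's V
#'
#' Builds the 2 x B contingency table (network x shared degree bin) of two
#' degree histograms, pools sparse bins from the high-degree tail downward
#' until every expected cell count reaches `min_expected` (the classical
#' validity rule), and reports the Pearson chi-squared homogeneity statistic
#' with `df = B - 1`, its upper-tail p-value, and Cramer's V
#' `sqrt(chi2 / (n_total (min(r, c) - 1)))` as the effect size.
#'
#' @param h1,h2 Two [degree_distribution()] histograms.
#' @param min_expected Minimum expected cell count before tail pooling
#'   stops (default 5).
#' @return A one-row tibble: `chi2`, `df`, `p`, `cramers_v`, `n_total`,
#'   `n_bins_used`.
#' @export
compare_degree_distributions <- function(h1, h2, min_expected = 5) {
  for (h in list(h1, h2)) {
    if (!all(c("degree", "count") %in% names(h)) || sum(h$count) == 0) {
      abort("each histogram needs degree/count columns and a positive total")
    }
  }
  degrees <- sort(unique(c(h1$degree, h2$degree)))
  o1 <- setNames(rep(0, length(degrees)), degrees)
  o2 <- o1
  o1[as.character(h1$degree)] <- h1$count
  o2[as.character(h2$degree)] <- h2$count
  tab <- rbind(o1, o2)

  # coarsen sparse bins by accumulating adjacent bins from the high-degree
  # tail downward until every expected cell count reaches min_expected
  n_all <- sum(tab)
  min_row_prop <- min(rowSums(tab)) / n_all
  B0 <- ncol(tab)
  group <- integer(B0)
  gid <- 1L
  acc <- 0
  for (b in B0:1) {
    acc <- acc + sum(tab[, b])
    group[b] <- gid
    if (acc * min_row_prop >= min_expected && b > 1L) {
      gid <- gid + 1L
      acc <- 0
    }
  }
  if (acc * min_row_prop < min_expected && gid > 1L) {
    group[group == gid] <- gid - 1L  # underfilled lowest-degree chunk
  }
  keep_order <- rev(unique(group))  # ascending degree
  tab <- vapply(keep_order, function(g) rowSums(tab[, group == g,
                                                    drop = FALSE]),
                numeric(2))
  if (is.null(dim(tab))) tab <- matrix(tab, nrow = 2)

  n_total <- sum(tab)
  B <- ncol(tab)
  if (B == 1L) {
    chi2 <- 0; df <- 0L; p <- 1; v <- 0
  } else {
    expected <- outer(rowSums(tab), colSums(tab)) / n_total
    chi2 <- sum((tab - expected)^2 / expected)
    df <- B - 1L
    p <- pchisq(chi2, df = df, lower.tail = FALSE)
    v <- sqrt(chi2 / (n_total * (min(dim(tab)) - 1)))
  }
  tibble(chi2 = chi2, df = as.integer(df), p = p, cramers_v = v,
         n_total = as.integer(n_total), n_bins_used = as.integer(B))
}

#' Cramer's V for an arbitrary contingency table
#'
#' Effect size `sqrt(chi2 / (n (min(r, c) - 1)))` of the Pearson
#' chi-squared statistic of an `r x c` table; 0 for independence, 1 for
#' perfect association.
#'
#' @param tab Numeric matrix of observed counts.
#' @return Cramer's V in `[0, 1]`.
#' @export
cramers_v <- function(tab) {
  stopifnot(is.matrix(tab), all(tab >= 0))
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  chi2 <- sum((tab - expected)^2 / expected, na.rm = TRUE)
  sqrt(chi2 / (n * (min(dim(tab)) - 1)))
}

#' Macroscale summary of a network and its partition
#'
#' Node and edge counts, edge density over the node universe, connected
#' component sizes, and (when a partition is supplied) module count and
#' module size distribution.
#'
#' @param network A network accepted by [visit_rates()].
#' @param partition Optional [mapeq_partition].
#' @return A list of class `network_summary`: `n_nodes`, `n_edges`,
#'   `density`, `component_sizes` (decreasing), `n_components`,
#'   `module_sizes`, `n_modules`.
#' @export
summarize_network <- function(network, partition = NULL) {
  net <- net_edges(network)
  n <- length(net$nodes)
  n_edges <- nrow(net$edges)
  density <- if (n < 2) 0 else n_edges / (n * (n - 1) / 2)
  if (n_edges > 0) {
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                       vertices = data.frame(name = net$nodes))
    comp <- igraph::components(g)
    comp_sizes <- sort(as.integer(comp$csize), decreasing = TRUE)
  } else {
    comp_sizes <- rep(1L, n)
  }
  module_sizes <- NULL
  n_modules <- NA_integer_
  if (!is.null(partition)) {
    module_sizes <- sort(as.integer(table(partition$module)),
                         decreasing = TRUE)
    n_modules <- length(module_sizes)
  }
  structure(
    list(n_nodes = n, n_edges = n_edges, density = density,
         component_sizes = comp_sizes, n_components = length(comp_sizes),
         module_sizes = module_sizes, n_modules = n_modules),
    class = "network_summary"
  )
}

#' @exportS3Method base::print
print.network_summary <- function(x, ...) {
  cat(sprintf("<network_summary> %d nodes, %d edges, density %.4g, %d components\n",
              x$n_nodes, x$n_edges, x$density, x$n_components))
  if (!is.null(x$module_sizes)) {
    cat(sprintf("  %d modules, largest %d\n", x$n_modules,
                max(x$module_sizes)))
  }
  invisible(x)
}

#' Overlay two cohort degree distributions
#'
#' Log-log scatter of the degree histograms of two networks, the standard
#' presentation for comparing connectivity patterns between cohorts.
#'
#' @param h1,h2 [degree_distribution()] histograms.
#' @param labels Length-2 character vector naming the two networks.
#' @return A ggplot object.
#' @export
plot_degree_comparison <- function(h1, h2, labels = c("early", "late")) {
  df <- rbind(
    tibble(degree = h1$degree, count = h1$count, network = labels[1]),
    tibble(degree = h2$degree, count = h2$count, network = labels[2])
  )
  ggplot(df, aes(x = .data$degree, y = .data$count,
                 colour = .data$network)) +
    geom_point(alpha = 0.8) +
    scale_x_log10() +
    scale_y_log10() +
    scale_colour_manual(values = setNames(c("blue", "red"), labels)) +
    labs(x = "node degree", y = "number of nodes", colour = "network") +
    theme_minimal()
}
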