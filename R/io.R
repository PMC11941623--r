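#' Read and write gene-by-sample count matrices
#'
#' Counts travel as tab-separated text: a header row of sample ids, a first
#' column of gene ids, and nonnegative integer counts. `write_counts()` and
#' `read_counts()` round-trip losslessly.
#'
#' @param path Path to a TSV file.
#' @return `read_counts()` returns an integer matrix with gene rownames and
#'   sample colnames; `write_counts()` returns `path` invisibly.
#' @examples
#' m <- matrix(0:5, 2, 3, dimnames = list(c("g1", "g2"), c("a", "b", "c")))
#' f <- tempfile(fileext = ".tsv")
#' write_counts(m, f)
#' all(read_counts(f) == m)
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(df) < 2L) abort("count TSV needs a gene-id column plus samples")
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes)) abort("duplicate gene ids in count matrix")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) abort("non-numeric entries in count matrix")
  if (any(is.na(m))) abort("missing values in count matrix")
  if (any(m < 0)) abort("negative entries in count matrix")
  storage.mode(m) <- "integer"
  rownames(m) <- genes
  m
}

#' @rdname read_counts
#' @param counts Integer matrix with gene rownames and sample colnames.
#' @export
write_counts <- function(counts, path) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  df <- as.data.frame(counts)
  df <- cbind(gene = rownames(counts), df)
  readr::write_tsv(as_tibble(df), path, progress = FALSE)
  invisible(path)
}

#' Read and write cohort designs
#'
#' The design is a two-(or three-)column TSV: `sample_id`, `group`
#' (`early`/`late`), optionally `age_at_diagnosis`.
#'
#' @param path Path to a TSV file.
#' @return `read_design()` returns a design tibble as produced by
#'   [assign_cohorts()]; `write_design()` returns `path` invisibly.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample_id", "group") %in% names(df))) {
    abort("design TSV needs columns sample_id and group")
  }
  if (!all(df$group %in% c("early", "late"))) {
    abort("design group labels must be 'early' or 'late'")
  }
  if (anyDuplicated(df$sample_id)) abort("duplicate sample ids in design")
  df$sample_id <- as.character(df$sample_id)
  df$group <- factor(df$group, levels = c("early", "late"))
  as_tibble(df)
}

#' @rdname read_design
#' @param design A design tibble.
#' @export
write_design <- function(design, path) {
  stopifnot(all(c("sample_id", "group") %in% names(design)))
  out <- design
  out$group <- as.character(out$group)
  readr::write_tsv(as_tibble(out), path, progress = FALSE)
  invisible(path)
}

#' Write a co-expression network as an edge-list TSV
#'
#' Columns `gene_a`, `gene_b`, `mi_bits`, `p_value`, one undirected edge per
#' row.
#'
#' @param network A [coexpression_network] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(network, path) {
  stopifnot(inherits(network, "coexpression_network"))
  readr::write_tsv(
    tibble(gene_a = network$edges$from, gene_b = network$edges$to,
           mi_bits = network$edges$weight, p_value = network$edges$p_value),
    path, progress = FALSE
  )
  invisible(path)
}

#' Write a network in GraphML format
#'
#' Co-expression networks are written with `mi` (bits) and `p_value` edge
#' attributes; bipartite module-function networks carry a `layer` node
#' attribute (`"module"` or `"term"`) and a `q` edge attribute.
#'
#' @param network A [coexpression_network] or `bipartite_network` object, or
#'   an igraph graph.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(network, path) {
  g <- as_igraph(network)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Convert package network objects to igraph graphs
#'
#' @param network A [coexpression_network] or `bipartite_network` object.
#' @return An igraph graph.
#' @export
as_igraph <- function(network) {
  if (igraph::is_igraph(network)) return(network)
  if (inherits(network, "coexpression_network")) {
    g <- igraph::graph_from_data_frame(
      d = data.frame(from = network$edges$from, to = network$edges$to,
                     mi = network$edges$weight,
                     p_value = network$edges$p_value),
      directed = FALSE,
      vertices = data.frame(name = network$nodes)
    )
    return(g)
  }
  if (inherits(network, "bipartite_network")) {
    mods <- sprintf("module_%s", network$module_nodes)
    terms <- as.character(network$term_nodes)
    g <- igraph::graph_from_data_frame(
      d = data.frame(from = sprintf("module_%s", network$edges$module),
                     to = as.character(network$edges$term),
                     q = network$edges$q),
      directed = FALSE,
      vertices = data.frame(
        name = c(mods, terms),
        layer = c(rep("module", length(mods)), rep("term", length(terms)))
      )
    )
    return(g)
  }
  abort("cannot convert this object to an igraph graph")
}

#' Write a module partition as a two-column TSV
#'
#' @param partition A [mapeq_partition] object (or `node`/`module` tibble).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  df <- if (inherits(partition, "mapeq_partition")) {
    tidy(partition)
  } else {
    as_tibble(partition)
  }
  stopifnot(all(c("node", "module") %in% names(df)))
  readr::write_tsv(df[, c("node", "module")], path, progress = FALSE)
  invisible(path)
}
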