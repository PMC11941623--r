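#' Gene-set collection
#'
#' A light container for annotation catalogues (KEGG pathways, GO terms,
#' synthetic planted terms, ...): a named list of gene-id vectors plus an
#' optional description per term. Term ids must be unique and every set
#' nonempty.
#'
#' @param sets Named list of character vectors of gene ids.
#' @param descriptions Optional named character vector of term descriptions;
#'   missing entries default to `"NA"`.
#' @return An object of class `gene_set_collection`.
#' @examples
#' gsc <- gene_set_collection(list(A = c("g1", "g2"), B = c("g2", "g3")))
#' length(gsc$sets)
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == "")) {
    abort("`sets` must be a named list of gene-id vectors")
  }
  if (anyDuplicated(names(sets))) abort("term ids must be unique")
  if (any(lengths(sets) == 0L)) abort("every gene set must be nonempty")
  sets <- lapply(sets, as.character)
  desc <- setNames(rep("NA", length(sets)), names(sets))
  if (!is.null(descriptions)) {
    keep <- intersect(names(descriptions), names(sets))
    desc[keep] <- descriptions[keep]
  }
  structure(list(sets = sets, descriptions = desc),
            class = "gene_set_collection")
}

#' @exportS3Method base::print
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets, %d distinct genes\n",
              length(x$sets), length(unique(unlist(x$sets)))))
  invisible(x)
}

#' @describeIn gene_set_collection One row per (term, gene) pair.
#' @param x A `gene_set_collection`.
#' @param ... Unused.
#' @export
tidy.gene_set_collection <- function(x, ...) {
  tibble(
    term = rep(names(x$sets), lengths(x$sets)),
    gene = unlist(x$sets, use.names = FALSE)
  )
}

#' Read and write gene sets in GMT format
#'
#' GMT is the tab-separated catalogue format used by most enrichment tools:
#' one term per line, fields `term`, `description`, then one gene id per
#' remaining field. Reading and writing round-trip losslessly.
#'
#' @param path Path to a `.gmt` file.
#' @return `read_gmt()` returns a [gene_set_collection()]; `write_gmt()`
#'   returns `path` invisibly.
#' @examples
#' gsc <- gene_set_collection(list(A = c("g1", "g2")))
#' f <- tempfile(fileext = ".gmt")
#' write_gmt(gsc, f)
#' read_gmt(f)
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) abort("empty GMT file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0L) {
    abort(sprintf("malformed GMT line %d: fewer than 3 tab-separated fields",
                  bad[1]))
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) abort("duplicate term ids in GMT file")
  sets <- setNames(lapply(fields, function(f) f[-(1:2)]), ids)
  desc <- setNames(vapply(fields, `[[`, character(1), 2L), ids)
  gene_set_collection(sets, desc)
}

#' @rdname read_gmt
#' @param gsc A [gene_set_collection()].
#' @export
write_gmt <- function(gsc, path) {
  stopifnot(inherits(gsc, "gene_set_collection"))
  lines <- vapply(names(gsc$sets), function(id) {
    paste(c(id, gsc$descriptions[[id]], gsc$sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
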