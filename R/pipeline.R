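#' Configuration of an end-to-end two-cohort run
#'
#' Validates and bundles every knob of [run_pipeline()]. Exactly one input
#' mode must be active: either paths to real data (`counts_path`,
#' `design_path`, `annotation_path`) or a simulation block (`sim`, a
#' [sim_params()] object).
#'
#' @param counts_path,design_path,annotation_path Paths to a counts TSV, a
#'   design TSV and a GMT catalogue (real-data mode).
#' @param sim A [sim_params()] object (simulation mode).
#' @param out_dir Output directory; created if missing.
#' @param age_cutoff Age-at-diagnosis cutoff in years (default 70).
#' @param min_cpm,min_samples Expression filter; `min_samples = NULL` uses
#'   the smaller cohort's size.
#' @param mi_percentile MI percentile kept as network edges (default 99).
#' @param n_bins MI bin count; `NULL` uses `floor(sqrt(n_samples))` per
#'   cohort.
#' @param n_trials Map-equation optimization trials (default 1000).
#' @param q_threshold BH significance threshold for enrichment edges.
#' @param min_module_size Smallest module tested for enrichment.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param verbose Echo log lines to the console?
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts_path = NULL, design_path = NULL,
                            annotation_path = NULL, sim = NULL,
                            out_dir = tempfile("coexcomp_run_"),
                            age_cutoff = 70, min_cpm = 1,
                            min_samples = NULL, mi_percentile = 99,
                            n_bins = NULL, n_trials = 1000,
                            q_threshold = 0.05, min_module_size = 10,
                            seed = 1L, verbose = FALSE) {
  real <- !is.null(counts_path) || !is.null(design_path) ||
    !is.null(annotation_path)
  simu <- !is.null(sim)
  if (real && simu) {
    abort("supply either real input paths or a simulation block, not both")
  }
  if (!real && !simu) sim <- sim_params(seed = seed)
  if (real) {
    if (is.null(counts_path) || is.null(design_path) ||
        is.null(annotation_path)) {
      abort("real-data mode needs counts_path, design_path and annotation_path")
    }
  }
  if (!is.null(sim) && !inherits(sim, "sim_params")) {
    abort("`sim` must be a sim_params() object")
  }
  if (mi_percentile <= 0 || mi_percentile >= 100) {
    abort("mi_percentile must lie strictly between 0 and 100")
  }
  if (q_threshold <= 0 || q_threshold >= 1) {
    abort("q_threshold must lie strictly between 0 and 1")
  }
  if (n_trials < 1) abort("n_trials must be >= 1")
  structure(
    list(counts_path = counts_path, design_path = design_path,
         annotation_path = annotation_path, sim = sim, out_dir = out_dir,
         age_cutoff = age_cutoff, min_cpm = min_cpm,
         min_samples = min_samples, mi_percentile = mi_percentile,
         n_bins = n_bins, n_trials = n_trials, q_threshold = q_threshold,
         min_module_size = min_module_size, seed = as.integer(seed),
         verbose = isTRUE(verbose)),
    class = "pipeline_config"
  )
}

#' Run the full two-cohort co-expression comparison
#'
#' Executes, in order: cohort assignment, low-expression filtering, TMM
#' normalization, negative-binomial exact-test differential expression with
#' BH control, fold-change gene-set perturbation scoring, per-cohort
#' mutual-information network inference at the configured percentile,
#' per-cohort map-equation modular decomposition, per-cohort hypergeometric
#' module enrichment with its bipartite module-function network, and the
#' cross-cohort degree-distribution comparison. All artifacts (TSV, GMT,
#' GraphML, MatrixMarket, JSON report, plain-text log) are written under
#' `config$out_dir`; the run is fully deterministic given `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `run_report`; see its `print()` method. Every
#'   number in the report is re-derivable from the emitted artifact files.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  cat(sprintf("coexcomp %s | run started %s | seed %d\n",
              as.character(packageVersion("coexcomp")),
              format(Sys.time(), "%Y-%m-%d %H:%M:%S"), config$seed),
      file = log_path)
  log_line <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    cat(msg, "\n", sep = "", file = log_path, append = TRUE)
    if (config$verbose) message(msg)
  }
  run_stage <- function(stage, expr) {
    log_line("[%s] start", stage)
    tryCatch(expr, error = function(e) {
      log_line("[%s] FAILED: %s", stage, conditionMessage(e))
      abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
    })
  }
  truth <- NULL

  inputs <- run_stage("input", {
    if (!is.null(config$sim)) {
      p <- config$sim
      ages <- withr::with_seed(stage_seed(config$seed, "ages"), {
        c(runif(p$n_early, config$age_cutoff - 15, config$age_cutoff - 1),
          runif(p$n_late, config$age_cutoff, config$age_cutoff + 25))
      })
      design <- assign_cohorts(ages, cutoff = config$age_cutoff)
      truth <- simulate_truth(p)
      counts <- simulate_counts(truth, design, p)
      annotation <- simulate_annotation(truth)
      write_counts(counts, file.path(config$out_dir, "counts.tsv"))
      Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE),
                      file.path(config$out_dir, "counts.mtx"))
      writeLines(rownames(counts),
                 file.path(config$out_dir, "counts_genes.txt"))
      writeLines(colnames(counts),
                 file.path(config$out_dir, "counts_samples.txt"))
      write_design(design, file.path(config$out_dir, "design.tsv"))
      write_gmt(annotation, file.path(config$out_dir, "annotation.gmt"))
      jsonlite::write_json(
        list(module_of = as.list(truth$module_of),
             de_genes = as.list(truth$de_genes),
             perturbed_sets = truth$perturbed_sets,
             library_sizes = truth$library_sizes),
        file.path(config$out_dir, "truth.json"), auto_unbox = TRUE,
        digits = NA)
    } else {
      counts <- read_counts(config$counts_path)
      design <- read_design(config$design_path)
      annotation <- read_gmt(config$annotation_path)
    }
    if (nlevels(droplevels(design$group)) < 2L) {
      abort("both cohorts must be nonempty")
    }
    list(counts = counts, design = design, annotation = annotation)
  })
  design <- inputs$design
  n_by_group <- table(design$group)
  log_line("[input] %d genes x %d samples (%d early, %d late)",
           nrow(inputs$counts), ncol(inputs$counts),
           n_by_group[["early"]], n_by_group[["late"]])

  counts <- run_stage("filter", {
    min_samples <- config$min_samples %||% min(n_by_group)
    filter_low_expression(inputs$counts, config$min_cpm, min_samples)
  })
  log_line("[filter] %d of %d genes kept (CPM >= %g in >= %d samples)",
           nrow(counts), nrow(inputs$counts), config$min_cpm,
           config$min_samples %||% min(n_by_group))

  factors <- run_stage("tmm", compute_tmm_factors(counts))
  log_line("[tmm] reference sample %s; factors in [%.3f, %.3f]",
           attr(factors, "reference_sample"), min(factors$tmm_factor),
           max(factors$tmm_factor))

  dge <- run_stage("dge", {
    phi <- estimate_common_dispersion(counts, design, factors)
    log_line("[dge] common dispersion %.4f", phi)
    out <- exact_test(counts, design, factors, phi)
    readr::write_tsv(as_tibble(out), file.path(config$out_dir, "dge.tsv"),
                     progress = FALSE)
    out
  })
  log_line("[dge] %d genes at FDR < 0.05", sum(dge$FDR < 0.05))

  logcpm <- cpm(counts, factors, log = TRUE)
  gage_res <- run_stage("gage", {
    fc <- gene_fold_changes(logcpm, design)
    out <- run_gage(fc, inputs$annotation)
    readr::write_tsv(
      out[, c("term", "set_size_used", "t_stat", "p_up", "q_up")],
      file.path(config$out_dir, "gage_up.tsv"), progress = FALSE)
    readr::write_tsv(
      out[, c("term", "set_size_used", "t_stat", "p_down", "q_down")],
      file.path(config$out_dir, "gage_down.tsv"), progress = FALSE)
    out
  })
  log_line("[gage] %d set(s) with q_up < 0.05",
           sum(gage_res$q_up < 0.05, na.rm = TRUE))

  per_cohort <- list()
  histograms <- list()
  for (cohort in c("early", "late")) {
    samples <- design$sample_id[design$group == cohort]
    network <- run_stage(paste0("network_", cohort), {
      net <- build_coexpression_network(
        logcpm[, samples, drop = FALSE],
        n_bins = config$n_bins, percentile = config$mi_percentile)
      write_edgelist(net, file.path(config$out_dir,
                                    sprintf("network_%s.tsv", cohort)))
      write_graphml(net, file.path(config$out_dir,
                                   sprintf("network_%s.graphml", cohort)))
      net
    })
    log_line("[network_%s] %d edges at MI >= %.4g bits (%d samples, %d bins)",
             cohort, nrow(network$edges), network$threshold_value,
             length(samples), network$n_bins)

    partition <- run_stage(paste0("modules_", cohort), {
      part <- optimize_partition(network, n_trials = config$n_trials,
                                 seed = stage_seed(config$seed,
                                                   paste0("mapeq_", cohort)))
      write_partition(part, file.path(config$out_dir,
                                      sprintf("partition_%s.tsv", cohort)))
      jsonlite::write_json(
        list(n_modules = attr(part, "n_modules"),
             description_length = attr(part, "description_length"),
             module_sizes = as.integer(table(part$module))),
        file.path(config$out_dir,
                  sprintf("partition_%s_summary.json", cohort)),
        auto_unbox = TRUE, digits = NA)
      part
    })
    log_line("[modules_%s] %d modules, description length %.3f bits",
             cohort, attr(partition, "n_modules"),
             attr(partition, "description_length"))

    enrichment <- run_stage(paste0("enrich_", cohort), {
      enr <- enrich_modules(partition, inputs$annotation,
                            universe = network$nodes,
                            min_module_size = config$min_module_size)
      readr::write_tsv(as_tibble(enr),
                       file.path(config$out_dir,
                                 sprintf("enrichment_%s.tsv", cohort)),
                       progress = FALSE)
      enr
    })
    bipartite <- build_bipartite(enrichment, config$q_threshold)
    write_graphml(bipartite,
                  file.path(config$out_dir,
                            sprintf("bipartite_%s.graphml", cohort)))
    log_line("[enrich_%s] %d enriched modules, %d distinct terms",
             cohort, length(bipartite$module_nodes),
             length(bipartite$term_nodes))

    histograms[[cohort]] <- degree_distribution(network)
    summ <- summarize_network(network, partition)
    per_cohort[[cohort]] <- tibble(
      cohort = cohort,
      n_samples = length(samples),
      n_genes = length(network$nodes),
      n_bins = network$n_bins,
      n_edges = nrow(network$edges),
      threshold_value = network$threshold_value,
      n_connected_nodes = sum(node_degrees(network) > 0),
      n_components = summ$n_components,
      n_modules = attr(partition, "n_modules"),
      description_length = attr(partition, "description_length"),
      n_enriched_modules = length(bipartite$module_nodes),
      n_distinct_terms = length(bipartite$term_nodes)
    )
  }

  comparison <- run_stage("compare", {
    cmp <- compare_degree_distributions(histograms$early, histograms$late)
    readr::write_tsv(cmp, file.path(config$out_dir, "comparison.tsv"),
                     progress = FALSE)
    cmp
  })
  log_line("[compare] chi2 = %.4g (df %d), Cramer's V = %.4f",
           comparison$chi2, comparison$df, comparison$cramers_v)

  report <- structure(
    list(
      version = as.character(packageVersion("coexcomp")),
      seed = config$seed,
      config = config[setdiff(names(config), "verbose")],
      n_genes_input = nrow(inputs$counts),
      n_genes_filtered = nrow(counts),
      n_dge_fdr05 = sum(dge$FDR < 0.05),
      n_gage_up05 = sum(gage_res$q_up < 0.05, na.rm = TRUE),
      n_gage_down05 = sum(gage_res$q_down < 0.05, na.rm = TRUE),
      cohorts = dplyr::bind_rows(per_cohort),
      comparison = comparison
    ),
    class = "run_report"
  )
  jsonlite::write_json(
    list(version = report$version, seed = report$seed,
         n_genes_input = report$n_genes_input,
         n_genes_filtered = report$n_genes_filtered,
         n_dge_fdr05 = report$n_dge_fdr05,
         n_gage_up05 = report$n_gage_up05,
         n_gage_down05 = report$n_gage_down05,
         cohorts = report$cohorts, comparison = report$comparison),
    file.path(config$out_dir, "report.json"), auto_unbox = TRUE,
    digits = NA)
  log_line("run finished")
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @exportS3Method base::print
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> coexcomp %s, seed %d\n", x$version, x$seed))
  cat(sprintf("  genes: %d input, %d after filter; DE at FDR<0.05: %d\n",
              x$n_genes_input, x$n_genes_filtered, x$n_dge_fdr05))
  print(x$cohorts)
  cat(sprintf("  degree comparison: chi2 = %.4g, V = %.4f, p = %.3g\n",
              x$comparison$chi2, x$comparison$cramers_v, x$comparison$p))
  invisible(x)
}

#' @describeIn run_pipeline Per-cohort observables as a tibble.
#' @param x A `run_report`.
#' @param ... Unused.
#' @export
tidy.run_report <- function(x, ...) {
  x$cohorts
}

#' @describeIn run_pipeline One-row cross-cohort summary.
#' @export
glance.run_report <- function(x, ...) {
  tibble(
    n_genes_filtered = x$n_genes_filtered,
    n_dge_fdr05 = x$n_dge_fdr05,
    n_modules_early = x$cohorts$n_modules[x$cohorts$cohort == "early"],
    n_modules_late = x$cohorts$n_modules[x$cohorts$cohort == "late"],
    n_terms_early = x$cohorts$n_distinct_terms[x$cohorts$cohort == "early"],
    n_terms_late = x$cohorts$n_distinct_terms[x$cohorts$cohort == "late"],
    chi2 = x$comparison$chi2,
    cramers_v = x$comparison$cramers_v
  )
}
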