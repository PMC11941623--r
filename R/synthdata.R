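#' Assign samples to onset cohorts by age at diagnosis
#'
#' Splits a set of samples into an early-onset and a late-onset cohort at an
#' age-at-diagnosis cutoff: a sample is `early` when its age at diagnosis is
#' strictly below the cutoff and `late` otherwise. The default cutoff of 70
#' years is the conventional boundary between early- and late-onset
#' Alzheimer's disease used throughout this package.
#'
#' @param ages Numeric vector of ages at diagnosis, in years. All must be
#'   positive and finite.
#' @param cutoff Age cutoff in years (default 70). Samples with
#'   `age < cutoff` are labelled `early`, samples with `age >= cutoff` `late`.
#' @param sample_id Optional character vector of sample identifiers; generated
#'   as `S001, S002, ...` when omitted.
#'
#' @return A tibble with columns `sample_id`, `age_at_diagnosis` and `group`
#'   (factor with levels `early`, `late`), carrying the cutoff as the
#'   `"cutoff"` attribute.
#' @examples
#' assign_cohorts(c(64, 70, 83))
#' @export
assign_cohorts <- function(ages, cutoff = 70, sample_id = NULL) {
  if (length(ages) == 0L) abort("empty design: no ages supplied")
  if (!is.numeric(ages) || any(!is.finite(ages)) || any(ages <= 0)) {
    abort("ages must be positive, finite numbers (years)")
  }
  if (is.null(sample_id)) {
    sample_id <- sprintf("S%03d", seq_along(ages))
  }
  if (length(sample_id) != length(ages)) {
    abort("`sample_id` and `ages` must have equal length")
  }
  if (anyDuplicated(sample_id)) abort("duplicate sample ids in design")
  design <- tibble(
    sample_id = as.character(sample_id),
    age_at_diagnosis = as.numeric(ages),
    group = factor(ifelse(ages < cutoff, "early", "late"),
                   levels = c("early", "late"))
  )
  attr(design, "cutoff") <- cutoff
  design
}

#' Simulation parameters for the two-cohort count generator
#'
#' Bundles and validates every knob of the synthetic two-cohort RNA-seq
#' generator. Defaults encode the study conditions the package is built
#' around: an imbalanced design of 47 early-onset versus 174 late-onset
#' samples, 2000 genes of which 5 modules of 20 genes are co-expressed
#' through a shared latent factor with loading `factor_loading`, a
#' negative-binomial dispersion of 0.1, 5% differentially expressed genes at
#' |log2 fold change| = 2, and library sizes drawn log-uniformly between one
#' and two million reads so that normalization factors are non-trivial.
#'
#' @param n_genes Number of genes in the universe.
#' @param n_modules Number of planted co-expression modules.
#' @param module_size Genes per planted module; `n_modules * module_size`
#'   must not exceed `n_genes`.
#' @param n_early,n_late Cohort sizes (defaults 47 and 174).
#' @param baseline_logmean_range Interval (natural-log relative expression)
#'   from which per-gene baseline log-means are drawn uniformly.
#' @param factor_loading Loading `rho` in `[0, 1]` of the shared per-module
#'   latent factor; 0 removes planted co-expression.
#' @param dispersion Negative-binomial dispersion `phi >= 0`; 0 gives Poisson
#'   counts.
#' @param de_fraction Fraction of genes that are differentially expressed
#'   between cohorts.
#' @param de_log2fc Magnitude of the planted log2 fold change.
#' @param libsize_range Interval (reads) for log-uniform library sizes.
#' @param n_true_terms Number of annotation terms copied from planted modules
#'   (must not exceed `n_modules`).
#' @param n_decoy_terms Number of decoy annotation terms of uniformly sampled
#'   genes.
#' @param seed Integer seed; every generator is a pure function of
#'   `(params, seed)`.
#'
#' @return A validated list of class `sim_params`.
#' @examples
#' sim_params(n_genes = 500, seed = 7)
#' @export
sim_params <- function(n_genes = 2000, n_modules = 5, module_size = 20,
                       n_early = 47, n_late = 174,
                       baseline_logmean_range = c(1, 6),
                       factor_loading = 0.8, dispersion = 0.1,
                       de_fraction = 0.05, de_log2fc = 2,
                       libsize_range = c(1e6, 2e6),
                       n_true_terms = 5, n_decoy_terms = 20,
                       seed = 1L) {
  p <- list(
    n_genes = as.integer(n_genes), n_modules = as.integer(n_modules),
    module_size = as.integer(module_size),
    n_early = as.integer(n_early), n_late = as.integer(n_late),
    baseline_logmean_range = as.numeric(baseline_logmean_range),
    factor_loading = as.numeric(factor_loading),
    dispersion = as.numeric(dispersion),
    de_fraction = as.numeric(de_fraction),
    de_log2fc = as.numeric(de_log2fc),
    libsize_range = as.numeric(libsize_range),
    n_true_terms = as.integer(n_true_terms),
    n_decoy_terms = as.integer(n_decoy_terms),
    seed = as.integer(seed)
  )
  if (p$n_genes < 1) abort("n_genes must be >= 1")
  if (p$n_modules < 0 || p$module_size < 1) {
    abort("n_modules must be >= 0 and module_size >= 1")
  }
  if (p$n_modules * p$module_size > p$n_genes) {
    abort("n_modules * module_size must not exceed n_genes")
  }
  if (p$de_fraction < 0 || p$de_fraction > 1) {
    abort("de_fraction must lie in [0, 1]")
  }
  if (p$dispersion < 0) abort("dispersion must be >= 0")
  if (p$factor_loading < 0 || p$factor_loading > 1) {
    abort("factor_loading must lie in [0, 1]")
  }
  if (length(p$baseline_logmean_range) != 2L ||
      diff(p$baseline_logmean_range) < 0) {
    abort("baseline_logmean_range must be an increasing interval")
  }
  if (length(p$libsize_range) != 2L || any(p$libsize_range <= 0) ||
      diff(p$libsize_range) < 0) {
    abort("libsize_range must be a positive increasing interval")
  }
  if (p$n_true_terms > p$n_modules) {
    abort("n_true_terms must not exceed n_modules")
  }
  if (p$n_true_terms < 0 || p$n_decoy_terms < 0) {
    abort("term counts must be >= 0")
  }
  structure(p, class = "sim_params")
}

# k distinct, evenly spaced indices out of 1..n, deterministic
even_indices <- function(n, k) {
  if (k <= 0) return(integer(0))
  if (k >= n) return(seq_len(n))
  idx <- unique(round(seq(1, n, length.out = k)))
  if (length(idx) < k) {
    idx <- sort(c(idx, setdiff(seq_len(n), idx)[seq_len(k - length(idx))]))
  }
  idx
}

#' Draw the ground truth of a synthetic two-cohort experiment
#'
#' Fixes everything downstream recovery tests need to know: which genes form
#' which co-expression module, which genes are differentially expressed (and
#' with what signed log2 fold change), which annotation term is a planted
#' perturbed set, per-sample library sizes, and an annotation catalogue of
#' true terms (copies of planted modules) plus decoy terms of uniformly
#' sampled genes.
#'
#' The first `n_modules * module_size` genes are partitioned into contiguous
#' modules `M1, M2, ...`; remaining genes are `background`. When the number
#' of differentially expressed genes (`round(de_fraction * n_genes)`) is at
#' least one module's size, all of module M1 is shifted up coherently by
#' `+de_log2fc` and its copying term is recorded as the planted perturbed
#' set; the remaining DE genes are spread evenly over background genes with
#' deterministically alternating signs, so expected up/down counts are exact.
#'
#' @param params A [sim_params()] object.
#' @return A list of class `synthetic_truth` with elements `module_of`
#'   (named character, gene to module id or `"background"`), `de_genes`
#'   (named numeric, signed log2 fold changes), `perturbed_sets` (character),
#'   `library_sizes` (numeric, one per sample), `annotation` (a
#'   [gene_set_collection()]) and `genes`.
#' @examples
#' truth <- simulate_truth(sim_params(n_genes = 200, seed = 3))
#' table(truth$module_of)
#' @export
simulate_truth <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  genes <- sprintf("g%04d", seq_len(params$n_genes))
  n_mod_genes <- params$n_modules * params$module_size
  module_of <- setNames(rep("background", params$n_genes), genes)
  if (n_mod_genes > 0) {
    module_of[seq_len(n_mod_genes)] <-
      rep(paste0("M", seq_len(params$n_modules)), each = params$module_size)
  }

  n_de <- round(params$de_fraction * params$n_genes)
  de_genes <- numeric(0)
  perturbed_sets <- character(0)
  plant_set <- n_de >= params$module_size && params$n_modules >= 1 &&
    params$n_true_terms >= 1
  if (plant_set) {
    set_genes <- genes[module_of == "M1"]
    de_genes <- setNames(rep(params$de_log2fc, length(set_genes)), set_genes)
    perturbed_sets <- "T1_M1"
    n_rest <- n_de - length(set_genes)
  } else {
    n_rest <- n_de
  }
  if (n_rest > 0) {
    pool <- genes[module_of == "background"]
    if (n_rest > length(pool)) pool <- setdiff(genes, names(de_genes))
    picked <- pool[even_indices(length(pool), n_rest)]
    signs <- rep_len(c(1, -1), length(picked))
    de_genes <- c(de_genes, setNames(signs * params$de_log2fc, picked))
  }

  withr::with_seed(stage_seed(params$seed, "truth"), {
    n_samples <- params$n_early + params$n_late
    library_sizes <- exp(runif(n_samples,
                               log(params$libsize_range[1]),
                               log(params$libsize_range[2])))
    sets <- list()
    descriptions <- character(0)
    for (k in seq_len(params$n_true_terms)) {
      id <- sprintf("T%d_M%d", k, k)
      sets[[id]] <- genes[module_of == paste0("M", k)]
      descriptions[id] <- sprintf("true term copying planted module M%d", k)
    }
    for (j in seq_len(params$n_decoy_terms)) {
      id <- sprintf("D%02d", j)
      sets[[id]] <- sort(sample(genes, min(params$module_size,
                                           params$n_genes)))
      descriptions[id] <- "decoy term of uniformly sampled genes"
    }
  })

  structure(
    list(
      genes = genes,
      module_of = module_of,
      de_genes = de_genes,
      perturbed_sets = perturbed_sets,
      library_sizes = library_sizes,
      annotation = gene_set_collection(sets, descriptions)
    ),
    class = "synthetic_truth"
  )
}

#' Simulate two-cohort negative-binomial counts with planted structure
#'
#' Draws a gene-by-sample count matrix from a latent-factor negative-binomial
#' model. Each module m contributes one standard-normal latent factor
#' `z[m, s]` per sample; gene g in sample s has NB mean
#' `L_s * exp(logmu_g + rho * z[m(g), s] + delta_g * x_s) / Z_s`, where `x_s`
#' indicates the late cohort, `delta_g` is the planted fold change on the
#' natural-log scale and `Z_s` rescales expected totals to the sample's
#' library size `L_s`. Counts are NB with dispersion `phi`
#' (`phi = 0` gives Poisson). The draw is a pure function of
#' `(truth, design, params$seed)`.
#'
#' @param truth A [simulate_truth()] object.
#' @param design A cohort design from [assign_cohorts()] with one row per
#'   library size in `truth`.
#' @param params The [sim_params()] used to build `truth`.
#' @return An integer matrix (genes x samples) with dimnames.
#' @examples
#' p <- sim_params(n_genes = 100, n_early = 4, n_late = 6, seed = 1)
#' truth <- simulate_truth(p)
#' design <- assign_cohorts(c(60, 62, 64, 66, 71, 75, 80, 85, 90, 95))
#' counts <- simulate_counts(truth, design, p)
#' dim(counts)
#' @export
simulate_counts <- function(truth, design, params) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(params, "sim_params"))
  if (nrow(design) != length(truth$library_sizes)) {
    abort("design and truth disagree on the number of samples")
  }
  genes <- truth$genes
  g <- length(genes)
  n <- nrow(design)
  delta <- setNames(numeric(g), genes)
  delta[names(truth$de_genes)] <- truth$de_genes * log(2)
  x_late <- as.numeric(design$group == "late")
  mod_ids <- unique(truth$module_of[truth$module_of != "background"])

  counts <- withr::with_seed(stage_seed(params$seed, "counts"), {
    logmu <- runif(g, params$baseline_logmean_range[1],
                   params$baseline_logmean_range[2])
    eta <- matrix(logmu, g, n) + outer(delta, x_late)
    if (length(mod_ids) > 0 && params$factor_loading > 0) {
      z <- matrix(rnorm(length(mod_ids) * n), length(mod_ids), n,
                  dimnames = list(mod_ids, NULL))
      in_mod <- truth$module_of != "background"
      eta[in_mod, ] <- eta[in_mod, , drop = FALSE] +
        params$factor_loading * z[truth$module_of[in_mod], , drop = FALSE]
    }
    w <- exp(eta)
    mu <- sweep(w, 2, truth$library_sizes / colSums(w), `*`)
    y <- if (params$dispersion == 0) {
      rpois(g * n, lambda = mu)
    } else {
      rnbinom(g * n, mu = mu, size = 1 / params$dispersion)
    }
    matrix(as.integer(y), g, n)
  })
  dimnames(counts) <- list(genes, design$sample_id)
  counts
}

#' Emit the annotation catalogue of a synthetic truth
#'
#' Returns the GMT-writable gene-set collection planted by
#' [simulate_truth()]: true terms exactly reproducing planted module
#' memberships plus decoy terms of uniformly sampled genes.
#'
#' @param truth A [simulate_truth()] object with a nonempty annotation.
#' @return A [gene_set_collection()].
#' @export
simulate_annotation <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (length(truth$annotation$sets) == 0L) {
    abort("truth carries an empty annotation catalogue")
  }
  truth$annotation
}

#' Simulate a planted-partition benchmark graph
#'
#' Undirected unweighted graph of `n_blocks` blocks of `block_size` nodes in
#' which within-block edges appear with probability `p_in` and between-block
#' edges with probability `p_out`. Used to benchmark community detection
#' against known blocks.
#'
#' @param n_blocks,block_size Number and size of planted blocks.
#' @param p_in,p_out Within- and between-block edge probabilities.
#' @param seed Integer seed.
#' @return A list with `edges` (tibble `from`, `to`, `weight` = 1) and
#'   `membership` (named integer, node to planted block).
#' @examples
#' g <- simulate_planted_partition(3, 10, 0.5, 0.02, seed = 1)
#' nrow(g$edges)
#' @export
simulate_planted_partition <- function(n_blocks = 4, block_size = 25,
                                       p_in = 0.3, p_out = 0.01, seed = 1L) {
  stopifnot(n_blocks >= 1, block_size >= 1,
            p_in >= 0, p_in <= 1, p_out >= 0, p_out <= 1)
  n <- n_blocks * block_size
  nodes <- sprintf("n%03d", seq_len(n))
  block <- rep(seq_len(n_blocks), each = block_size)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  same <- block[pairs[, 1]] == block[pairs[, 2]]
  keep <- withr::with_seed(stage_seed(seed, "planted_partition"), {
    runif(nrow(pairs)) < ifelse(same, p_in, p_out)
  })
  list(
    edges = tibble(
      from = nodes[pairs[keep, 1]],
      to = nodes[pairs[keep, 2]],
      weight = 1
    ),
    membership = setNames(block, nodes)
  )
}
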