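# coexcomp

Compare the gene co-expression networks of two patient cohorts built from
bulk RNA-seq counts — for example early-onset versus late-onset Alzheimer's
disease, split at an age-at-diagnosis cutoff of 70 years — and quantify how
their modular and functional organisation differs.

The package is aimed at computational biologists who have a gene-by-sample
count matrix, a sample sheet with ages at diagnosis, and a gene-set
catalogue (GMT), and who want a reproducible, testable version of the
classic network-comparison workflow:

1. **Normalization and differential expression.** Trimmed mean of M-values
   (TMM) scaling factors; a negative-binomial conditional exact test between
   cohorts with a method-of-moments common dispersion; Benjamini–Hochberg
   FDR control.
2. **Gene-set perturbation.** Per-set Welch *t* statistics of fold changes
   against the all-gene background, with separate up- and down-regulation
   tails, so oppositely regulated pathway arms remain visible.
3. **Co-expression networks.** Per-cohort pairwise mutual information
   I(X;Y) = Σ p(x,y) log₂[p(x,y)/(p(x)p(y))] on equal-frequency-discretized
   log-CPM, thresholded at the 99th percentile of all pair values. Each
   edge carries an analytic p-value through the likelihood-ratio identity
   G = 2·n·ln2·I, with G ~ χ² under independence.
4. **Modular decomposition.** Two-level map equation
   L = q↷H(Q) + Σᵢ pᵢ↻H(Pⁱ), minimized by a multi-trial Louvain-style
   greedy search (compiled, deterministic given a seed).
5. **Module function.** Hypergeometric over-representation of each module
   against the catalogue, BH-adjusted jointly, projected into a bipartite
   module–term network.
6. **Topology comparison.** Degree distributions of the two networks
   compared by a Pearson χ² homogeneity test with Cramér's V
   (√(χ²/(n·(min(r,c)−1)))) as effect size.

A synthetic-data generator with planted co-expression modules, planted
differentially expressed genes, a planted perturbed gene set and a matched
annotation catalogue gives every stage a recovery test with no external
data; real cohorts such as ROSMAP are controlled-access and are read from
the same TSV/GMT formats when available.

## Worked example

```r
library(coexcomp)

params <- sim_params(n_genes = 500, n_early = 20, n_late = 40, seed = 1)
truth  <- simulate_truth(params)
design <- assign_cohorts(c(seq(56, 69, length.out = 20),
                           seq(70, 92, length.out = 40)))
counts <- simulate_counts(truth, design, params)

factors <- compute_tmm_factors(counts)
phi     <- estimate_common_dispersion(counts, design, factors)
dge     <- exact_test(counts, design, factors, phi)
glance(dge)
#> # A tibble: 1 × 4
#>   n_genes n_fdr_05 dispersion orientation
#>     <int>    <int>      <dbl> <chr>
#> 1     500       45      0.272 late_over_early
```

45 of 500 genes reach FDR < 0.05; the generator planted 25
(`de_fraction = 0.05`, all recovered) and the remainder reflect the shared
latent-factor variation of module genes. The top genes carry the planted
|log2FC| = 2:

```r
head(dplyr::arrange(tibble::as_tibble(dge), FDR), 3)
#>   gene  logFC logCPM   PValue      FDR
#> 1 g0201 -2.03   10.7 1.47e-27 7.34e-25
#> 2 g0400 -1.84   11.6 9.20e-21 2.30e-18
#> 3 g0300  2.10   11.9 6.03e-20 1.01e-17
```

One MI network per cohort, its modules, and their functions:

```r
logcpm   <- cpm(counts, factors, log = TRUE)
net_late <- build_coexpression_network(logcpm[, design$group == "late"])
net_late
#> <coexpression_network> 500 nodes, 1257 edges (MI >= 0.9473 bits, 99th percentile)

part <- optimize_partition(net_late, n_trials = 100, seed = 1)
glance(part)
#> # A tibble: 1 × 5
#>   n_modules description_length n_nodes max_module_size median_module_size
#> 1        66               4.93     420              29                  5

enr <- enrich_modules(part, simulate_annotation(truth),
                      universe = net_late$nodes)
build_bipartite(enr)
#> <bipartite_network> 5 modules, 5 terms, 5 enrichment edges (q < 0.05)
```

All five planted modules surface as map-equation modules significantly
enriched for exactly their own planted terms; none of the 20 decoy terms
attach. `autoplot(dge)` draws the volcano plot,
`plot_degree_comparison(h1, h2)` overlays two cohort degree distributions,
and `run_pipeline(pipeline_config(...))` chains the whole analysis with
TSV/GMT/GraphML/JSON artifacts and a plain-text log
(`inst/scripts/run_pipeline.R` wraps it for the shell).

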