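---
title: "Methods: two-cohort co-expression network comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-cohort co-expression network comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

coexcomp compares the transcriptomes of two patient cohorts at three levels
— individual genes, gene sets, and co-expression network structure. This
vignette records the models behind each stage, the parameters that matter,
the numerical choices that were genuinely open, and what the synthetic
benchmark does and does not establish.

## Cohort definition

Samples are split on age at diagnosis: `early` strictly below the cutoff,
`late` at or above it. The default cutoff of 70 years follows the
epidemiological convention separating early- from late-onset Alzheimer's
disease; it is a parameter (`age_cutoff`) because other studies cut at 65.
The two-cohort design is deliberately imbalanced in the default synthetic
study (47 vs 174 samples), mirroring the scarcity of early-onset cases in
real aging cohorts: every downstream method must remain calibrated under
that imbalance, and the tests check it there.

## Normalization and differential expression

**TMM.** Between-sample scaling factors are trimmed means of M-values: per
sample against a reference, genewise log2 expression ratios (M) are trimmed
30% on each side by M and 5% by average log expression (A), and the
survivors averaged with inverse-variance binomial weights; factors are
recentred to geometric mean 1. The reference is the sample whose
75th-percentile CPM is closest to the mean of those percentiles — the
standard convention. The test suite checks both a hand-evaluated fixture
and exact agreement with the reference implementation in edgeR.

**Dispersion.** A single common negative-binomial dispersion is estimated
by the method of moments on group-centred, library-scaled counts: the mean
over genes of (s² − μ̂)/μ̂², floored at zero, over genes with mean
normalized count of at least 1 (below that the moment ratio is numerically
unstable and nearly information-free). This is intentionally simpler than
the shrinkage estimators of dedicated DE tools: a common dispersion is
sufficient for the pipeline's comparative purpose, is directly testable
(simulated Poisson data must yield φ̂ ≈ 0, simulated φ = 0.2 data must
yield φ̂ ∈ [0.15, 0.25]), and avoids presenting a re-implementation of a
specific shrinkage scheme as that scheme. Note that planted co-expression
(shared latent factors) inflates the effective dispersion; the estimator
reports total extra-Poisson variation, which is what the exact test needs
for calibration.

**Exact test.** Counts are scaled to the geometric-mean effective library,
summed per cohort, and rounded; under a common per-sample mean the group
sums are negative binomial with sizes n₁/φ and n₂/φ (Poisson at φ = 0),
and the reported p-value is the conditional probability, given the total,
of all outcomes as likely or less likely than the one observed. With
φ = 0, equal libraries and one sample per group this reduces exactly to
the two-sided binomial test — the unit tests pin that identity. The
enumeration window covers the 10⁻¹³ quantile range of both conditional
margins (always extended to include the observed outcome); mass outside it
is below reporting precision. Fold changes are late-over-early on
normalized group means with a prior count of 0.5 per group, so they are
finite at zero counts. Under a global-null simulation at the study design
(φ = 0.1, 47 vs 174 samples, 10000 genes) the fraction of p < 0.05 lands
near 0.05, and planted 4-fold genes are recovered with sensitivity above
0.8 at BH q < 0.05 — both are acceptance tests.

**Filtering.** Genes must reach `min_cpm` (default 1) in at least
`min_samples` samples, defaulting to the smaller cohort's size, so a gene
expressed in only the minority cohort survives.

## Gene-set perturbation

Per-gene fold changes (difference of group means of log2 CPM) are compared
set-against-background with a Welch two-sample t statistic and
Satterthwaite degrees of freedom; upper- and lower-tail probabilities are
reported separately so a pathway with oppositely regulated arms is visible
in both directions, and BH adjustment runs per direction across sets. The
background includes the set itself by default (the generally applicable
set-test convention; `exclusive_background = TRUE` removes it). A
paired-column mode — every test column against every reference column,
Stouffer-combined — is available (`run_gage_paired()`) since the
group-versus-pair choice is not fixed by convention; the group mode is the
default because it is deterministic in the design and cheap at 47 × 174.

## Mutual-information networks

Expression (log2 CPM by default; the estimator is rank-based per gene, so
any monotone per-gene transform of normalized expression gives the same
bins) is discretized per gene into `floor(sqrt(n_samples))` equal-frequency
bins — the common default for plug-in MI estimation, balancing resolution
against table sparsity. Ties are broken by stable input order; an entirely
constant gene collapses into one bin and has MI 0 with everything. Pairwise
MI is the plug-in estimate in bits, computed in compiled code for all
g(g−1)/2 pairs; a Miller–Madow bias correction is available behind a flag
but off by default, since thresholding by percentile is invariant to any
shift that is approximately common across pairs.

Each cohort's network keeps the pairs at or above the 99th percentile of
its own MI distribution (per-network thresholds, since the cohorts have
different sample counts and hence different MI noise floors). The
percentile is computed by linear interpolation between order statistics
(R's default quantile type 7); this matters because edge counts at the 1%
tail are sensitive to the convention, so it is recorded in the network
object. The tie rule is inclusive (mi ≥ threshold), so the degenerate
all-equal case keeps every edge. Edge significance is analytic through the
G-statistic identity G = 2·n·ln2·I with a χ² null on (r−1)(c−1) degrees of
freedom; it is reported as provenance and deliberately not used for
filtering — at these sample sizes essentially every retained edge has a
vanishingly small p-value, which is why the percentile, not the p-value,
defines the network.

## Map-equation modules

Modules minimize the two-level map equation
L = q↷H(Q) + Σᵢ pᵢ↻H(Pⁱ), the expected description length per step of a
random walk encoded with one index codebook and one codebook per module.
For undirected weighted graphs the walk's stationary distribution is
closed-form (visit rate = strength/2W), so no power iteration or
teleportation is needed. The optimizer runs `n_trials` independent trials
(default 1000, matching the convergence practice of iterating the
stochastic search many times and keeping the best): each trial shuffles
node order, greedily moves single nodes to neighboring or fresh modules
when L drops, aggregates modules into supernodes and repeats, then
finishes with a node-level refinement pass on the original graph. Greedy
ties go to the lowest module id and the per-trial RNG is seeded from
(seed, trial), so results are bit-reproducible. The one-module partition is
always a candidate, so the returned length never exceeds it. Only the flat
two-level variant is implemented — the comparison of interest is module
counts and sizes, not hierarchy. Isolated nodes are dropped before
optimization (configurable), since a node without flow has no codeword.

Correctness is pinned two ways: exhaustive enumeration of all set
partitions on 50 random graphs of up to 7 nodes (the greedy search must
attain the exact minimum), and recovery of planted 4 × 25 partitions at
p_in = 0.3, p_out = 0.01 with normalized mutual information ≥ 0.9.

## Module function and the bipartite projection

Each module of at least `min_module_size` genes (default 10; smaller
modules give unstable enrichment) is tested against every catalogue term by
the hypergeometric upper tail, with the universe restricted to the genes of
the analyzed network — the conservative choice; a whole-genome universe
would manufacture significance from the network's gene selection. BH runs
jointly over all module × term tests (one family; a per-module alternative
sits behind a flag). Rows with q < 0.05 become the edges of a strictly
two-layer module–term network, exported to GraphML with a `layer`
attribute. Terms are flat sets: no ontology traversal or term-ancestry
propagation is attempted.

## Degree-distribution comparison

Unweighted degrees of the thresholded networks are binned at unit width;
the 2 × B cohort-by-degree table is tested for homogeneity with Pearson's
χ² (df = B − 1) and summarized by Cramér's V. Sparse bins are coarsened by
accumulating adjacent bins from the high-degree tail downward until every
expected cell reaches 5 (the classical validity rule), with an underfilled
lowest chunk merged into its neighbor; the number of bins actually used is
reported. Degrees are taken over nodes with at least one edge, matching
how thresholded networks are drawn; the isolated remainder of the gene
universe is available behind a flag.

## The synthetic study

The generator emulates the features the pipeline must detect, with one
knob per feature:

* two cohorts of 47 and 174 samples (the default imbalance), ages drawn
  on either side of the 70-year cutoff;
* negative-binomial counts (dispersion φ = 0.1, Poisson at 0) with
  library sizes log-uniform on 1–2 million reads, forcing non-trivial TMM
  factors;
* five planted 20-gene modules driven by one shared standard-normal latent
  factor each, entering the gene's log-mean with loading ρ (default 0.8) —
  a single tunable difficulty knob for network recovery;
* 5% differentially expressed genes at |log2FC| = 2: one whole module
  shifted coherently upward (the planted perturbed set, giving the set
  test a positive control), the remainder spread evenly over background
  genes with deterministically alternating signs so expected up/down
  counts are exact;
* an annotation catalogue of the five true terms (exact module copies)
  plus 20 decoy terms of uniformly sampled genes.

The 2000-gene universe is a scale choice that keeps the full pipeline
inside a few minutes; the recovery acceptance run uses a 200-gene universe
(100 module genes plus 100 background genes) so that decoy pairs vastly
outnumber planted pairs and an 80% intra-module edge fraction is a
non-trivial claim.

What passing does **not** show: the generator has no batch effects, no
cell-type mixtures, no realistic marginal distributions, and its background
genes are mutually independent — so the default 99th-percentile network on
2000 mostly-independent genes is noise-dominated outside the planted
modules and its module decomposition is correspondingly coarse. Results on
real brain transcriptomes, where co-expression is pervasive, will have far
richer modular structure; the synthetic study validates the machinery, not
the biology.

## Determinism and problem sizes

Every stochastic step derives its seed from one master seed via a stage
hash (kept below 2³¹), including the compiled 1000-trial optimizer, so
`run_pipeline()` is bit-reproducible end to end — the acceptance suite
runs the default study twice and compares artifacts byte for byte. The
test suite's problem sizes (10000 genes for null calibration, 2000 for the
default study, 200 for network recovery, graphs of ≤ 7 nodes for
exhaustive enumeration) were chosen so the whole suite completes in a few
minutes on a single core while keeping each claim statistically meaningful.

## Known limitations

* The common-dispersion exact test ignores tagwise dispersion variation
  and covariates; it is a comparative screen, not a full GLM framework.
* Scaling pseudo-counts to a common library before summing is a moderate
  approximation to exact quantile adjustment; the global-null acceptance
  test bounds its practical effect.
* MI significance is asymptotic (χ²); at very small n with many bins it is
  anti-conservative, which is one more reason p-values do not gate edges.
* The map-equation search is greedy: optimality is proven only on the
  enumerable graphs of the acceptance suite, elsewhere it is a
  best-of-n-trials heuristic, as is standard.
* No batch-effect correction stage is included; if batch structure exists
  it must be handled upstream.
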