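---
title: "Methods and design of otukit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of otukit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otukit)
```

# The problem otukit addresses

Marker-gene surveys of microbial communities produce an abundance table of
operational taxonomic units (OTUs) by samples, usually accompanied by sample
covariates, taxonomic assignments, a phylogenetic tree over the OTUs, and
sometimes representative sequences. These components come from different
tools in different files, and almost every analysis step — filtering,
agglomeration, distances, ordination, testing — touches several of them at
once. otukit stores them in one container (`mb_experiment`) whose constructor
is the single place where consistency is enforced: component ID sets are
intersected, everything is reordered to the abundance table's order, and all
subsequent subsetting (`prune_taxa()`, `prune_samples()`, `merge_taxa()`)
propagates across every component automatically.

Two design choices in the container deserve comment:

* **Tolerant assembly.** `build_experiment()` intersects taxon/sample ID sets
  rather than demanding equality, logging how many IDs each component lost.
  Multi-source data almost never aligns exactly (a tree built on a superset
  of OTUs, metadata for samples that failed sequencing), so a strict
  constructor would force every user to pre-align by hand. An *empty*
  intersection is a hard error naming the offending component pair.
* **Canonical orientation.** Abundance tables arrive in both orientations;
  the `taxa_are_rows` flag records the source convention, but internally the
  matrix is always taxa x samples so that every algorithm has one code path.
* **Tree pruning contracts degree-2 nodes** by summing the adjacent branch
  lengths, which keeps patristic distances among the retained tips exactly
  invariant — a requirement for UniFrac and tip agglomeration to be
  subset-stable.

# Preprocessing

`transform_counts()` covers the standard per-sample normalisations (relative
abundance, log of base *b* via `log(1+x)/log(b)`, within-sample ranks with
average ties, and real-valued scaling of every sample to a common total).
`rarefy_even_depth()` is the subsampling variant: every sample is drawn down
to exactly `depth` counts, without replacement by default. Samples below the
target are dropped with a logged warning, and taxa left all-zero are removed.
The seed is a **required argument** everywhere randomness enters this package
— rarefaction, NMDS, permutation tests, layouts, simulation. An unseeded
rarefaction is unreproducible in a way that silently contaminates every
downstream result, so there is deliberately no default.

Two filters mirror the common "trim rare and flat OTUs" recipe:
`filter_taxa_k_over_a(exp, k_fraction, a)` keeps taxa whose count exceeds
`a` in at least `ceiling(k_fraction * n_samples)` samples (so "observed at
least 3 times in 20% of samples" is `k_fraction = 0.2, a = 2`, following the
kOverA convention from the microarray filtering tradition in which
"at least 3" means strictly more than 2), and `filter_taxa_cv(exp, cv_min)`
keeps taxa whose coefficient of variation (sample standard deviation with the
n-1 denominator, divided by the mean) exceeds `cv_min`. Both are strict
inequalities; both error when nothing survives.

Agglomeration reduces taxa either by shared taxonomy (`tax_glom()`: identical
assignments from the coarsest rank down to the requested rank) or by
phylogenetic proximity (`tip_glom()`: complete-linkage clustering of the
cophenetic distance matrix cut at height `h`). Complete linkage was chosen
because it guarantees that every pair of merged tips is within `h` of each
other; single or average linkage can chain together tips arbitrarily far
apart, which defeats the purpose of a distance bound. Both routes share
`merge_taxa()`, whose archetype is the most abundant member with ties broken
by the lexicographically smallest ID, so agglomeration is deterministic and
conserves per-sample totals exactly.

# Distances

`distance()` dispatches over a 44-name registry: 16 quantitative
dissimilarities computed by `vegan::vegdist`, the 24 classical
presence/absence incidence indices of `vegan::betadiver` (each defined by its
published formula), the Jensen-Shannon divergence, and three phylogenetic
distances computed natively — unweighted UniFrac, weighted UniFrac, and the
DPCoA distance.

UniFrac is implemented in the "Fast" formulation: `branch_abundance()` makes
one post-order traversal of the rooted tree and stores, for every branch, its
length and the per-sample total abundance of the tips below it
(O(edges x samples)). Every pairwise distance is then a sum over branches
that reuses this table. For samples A and B with per-branch descendant totals
$A_i, B_i$, totals $A_T, B_T$, branch lengths $b_i$ and root-to-tip depths
$d_j$:

* unweighted: $\sum_i b_i\,[\text{present in exactly one}] \,/\,
  \sum_i b_i\,[\text{present in at least one}]$;
* weighted (raw): $\sum_i b_i\,|A_i/A_T - B_i/B_T|$;
* weighted (normalized): the raw value divided by
  $D = \sum_j d_j (A_j/A_T + B_j/B_T)$, its maximum attainable value,
  so results lie in $[0, 1]$.

Unrooted trees are midpoint-rooted deterministically before the traversal
(a random root would silently break reproducibility); zero-length branches
contribute nothing; a sample with zero total abundance is an error naming the
sample, never a silent `NaN`. The set of sample pairs can be split into
chunks computed independently (`chunks` argument) — the merge is
bitwise-identical to the serial result, which is the contract a parallel
scheduler needs.

The DPCoA distance uses the identity
$d^2(k, l) = -\tfrac12 (p_k - p_l)^\top D (p_k - p_l)$ with $D$ the patristic
distance matrix and $p$ the relative-abundance profiles; this equals the Rao
dissimilarity between the two communities and also the full-space sample
distance of the DPCoA ordination below, so the distance and the ordination
are mutually consistent by construction.

# Ordination

`ordinate()` dispatches to seven engines. The eigen-engines are implemented
directly (they are small, and the tests pin them to independent oracles);
the NMDS optimiser is `vegan::monoMDS`.

* **CA** — SVD of the standardized residuals of the correspondence matrix,
  $(P - rc^\top)/\sqrt{rc^\top}$. Eigenvalues are squared singular values and
  sum to the total inertia $\chi^2/N$ (asserted to 1e-10 against
  `chisq.test`). Scores are reported in *symmetric* scaling (both sides
  scaled by $\sqrt{d}$): no scaling convention is canonical, and symmetric
  scaling keeps sample and taxa scores in compatible spaces for biplots.
* **PCoA** — double centering of $-d^2/2$ and eigendecomposition. Negative
  eigenvalues (non-Euclidean input) are *retained and reported* with a logged
  warning; coordinates are returned only for positive axes. No Lingoes or
  Cailliez correction is applied — corrections change the geometry and should
  be an explicit caller decision, not a silent default.
* **NMDS** — Kruskal stress-1 minimised by monotone regression, best of one
  PCoA-initialized start plus `n_starts = 20` seeded random starts,
  `tol = 1e-7` on the relative stress ratio. The final configuration is
  centered and rotated to principal axes. The returned stress can be audited
  independently with `kruskal_stress1()`, which is invariant under rotation
  and reflection of the configuration.
* **PCA** — `prcomp` with the usual center/scale switches; eigenvalues are
  score variances, and scaling a zero-variance column is an error.
* **RDA / CCA** — least-squares projection of the (centered, or chi-square
  standardized and row-weighted for CCA) profile matrix onto the span of the
  constraint variables, followed by SVD of the fitted and residual parts.
  Because fitted and residual are orthogonal, constrained plus unconstrained
  inertia equals the total exactly; tests assert agreement with `vegan::rda`
  and `vegan::cca` to 1e-8.
* **DPCoA** — taxa embedded by PCoA of square-root patristic distances (so
  squared embedding distances equal patristic distances), samples placed at
  the abundance-weighted centroids of their taxa, then a PCA of the sample
  cloud weighted by sample relative totals. If the square-root patristic
  matrix is not Euclidean-embeddable (numerically inconsistent branch
  lengths) the error says so and suggests checking the tree.
* **DCA** is deliberately not implemented: detrending-by-segments is a large,
  idiosyncratic algorithm orthogonal to this package's purpose, and a wrong
  reimplementation is worse than an explicit error pointing users elsewhere.

# Alpha diversity and testing

`estimate_richness()` reports Observed richness, bias-corrected Chao1
($S_{obs} + F_1(F_1-1)/(2(F_2+1))$, defined also when $F_2 = 0$, unlike the
classical $F_1^2/2F_2$ form), ACE with the standard rare/abundant partition
at 10, Shannon ($-\sum p \ln p$) and Simpson ($1 - \sum p^2$). Chao1 and ACE
(with their standard errors) come from `vegan::estimateR`, which implements
exactly these forms; Chao1/ACE require integer counts and refuse transformed
data.

`mt_minp()` tests every taxon for association with a categorical sample
variable under a permutation null, controlling the family-wise error rate
with the Westfall-Young step-down minP procedure. Statistics are the one-way
ANOVA F (any number of levels) or pooled/Welch t (two levels), two-sided via
the absolute value. Design decisions:

* Labels are permuted jointly across taxa, preserving the between-taxon
  dependence that minP exists to exploit.
* Raw p-values use the $(1 + \#\{|s_b| \ge |s_{obs}|\})/(B+1)$ convention: the
  observed labelling counts as one of the $B+1$ permutations, so p-values are
  never zero and the joint null distribution lives on the same grid as the
  raw p-values. (Computing the null matrix from the B random permutations
  alone lets the top taxon's adjusted p collapse to the raw granularity and
  measurably inflates the FWER.)
* Adjusted p-values are successive minima of the per-permutation p-value
  rows taken from the least significant taxon upward, with step-down
  monotonicity enforced and `adj_p >= raw_p` guaranteed.
* A taxon with no variance anywhere gets statistic 0 and p = 1, never `NaN`.
* `exact = TRUE` enumerates all $n!$ label permutations for small designs,
  which the tests use as an enumeration oracle.

Calibration is checked by simulation: 200 null data sets (generator below,
`effect_size = 1`, 20 samples, 50 taxa, B = 999) must give an empirical FWER
at $\alpha = 0.05$ inside the 95% binomial band around 0.05. The statistics
are computed for all taxa and all permutations from group sums via matrix
products, so a replicate costs a few milliseconds and the whole calibration
runs in seconds.

`hypergeom_enrichment()` is the upper-tail hypergeometric
(one-sided Fisher) test for overrepresentation of a category among selected
taxa, evaluated exactly via `phyper`.

# Visualization layouts

The six `*_plot_data`/layout functions compute *data*, not pictures: labeled
tables that any plotting layer can render. All are pure functions of
(experiment, parameters, seed) and the tests assert rerun equality.

* `ordination_plot_data()` joins coordinates with sample variables or
  taxonomy for samples-only, taxa-only, biplot and split displays, plus scree
  proportions over the positive eigenvalues.
* `heatmap_order()` orders samples (and optionally taxa) by the angle
  `atan2(axis2, axis1)` of their position in the first two ordination axes
  (NMDS of Bray-Curtis by default) — the ordination-driven alternative to
  dendrogram leaf orders, which can place deeply-split elements side by side.
  The angle sort is ascending in $(-\pi, \pi]$ with ties broken by ID.
  Distance-based ordinations carry no taxa scores, so taxa are ordered by the
  same method applied to distances among taxa over the transposed table;
  tree-based distances have no taxa-space analogue and are rejected.
* `make_network()` connects units whose distance is strictly below
  `max_dist` (defaults jaccard/0.4, which gives informative sparsity on the
  bundled generator; both values are echoed in CLI output headers because no
  default threshold is universally sensible). `network_layout()` is a seeded
  Fruchterman-Reingold layout centered at the origin.
* `tree_plot_data()` lays out a phylogram (tips at integer heights in
  postorder order, internal nodes at the mean of their children, horizontal
  position = cumulative branch length) and emits one marker per
  (tip, sample with count > 0) in successive offset columns beside the tips.
  Above 200 tips it logs a readability warning rather than refusing.
* `bar_plot_data()` aggregates per (x, fill) cell and stacks segments in
  decreasing abundance so the bar height equals the group total;
  `richness_plot_data()` is the long-format join of `estimate_richness()`
  with grouping variables, with standard errors only where the estimator has
  one (Chao1, ACE).

# The synthetic generator

`simulate_experiment()` draws one Dirichlet(1) base proportion vector,
multiplies the first `effect_taxa` components by `effect_size` in every
second group (renormalizing), and draws each sample as a multinomial of size
`depth` — so column sums are exactly `depth`, matching the even-depth
assumption of several downstream methods, which per-taxon Poisson sampling
would only satisfy on average. `effect_size = 1` makes the groups
exchangeable by construction: the null configuration used for FWER
calibration. A coalescent random tree with exponential branch lengths
(mean 0.1) and a hierarchically consistent taxonomy are attached.

What the generator does *not* emulate: zero inflation, overdispersion beyond
the multinomial, taxon-taxon correlation beyond compositional closure, or any
phylogenetic signal in the abundances (the tree is independent of the
counts). Passing tests therefore demonstrate algorithmic correctness and
calibration under clean multinomial sampling, not robustness to the messier
error structure of real surveys. One consequence visible in the tests:
because proportions renormalize, a strong effect on a few taxa slightly
shifts *all* taxa between groups, so "effect taxa top the F ranking" holds in
expectation rather than in every replicate.

Problem sizes used in the shipped tests (chosen to exercise each property at
the smallest informative scale): oracle comparisons on trees of 3-8 tips
across 100 seeds, the parallel-merge contract on a 50-sample experiment, and
FWER calibration with 200 replicates of a 50 x 20 null experiment at B = 999.

# Reproducibility and the CLI

Every stochastic entry point takes a mandatory seed; the CLI refuses to run
stochastic subcommands without `--seed`, and identical seeds produce
byte-identical outputs. The CLI (`run_cli()`, shipped as the
`inst/scripts/otukit` Rscript) moves serialized *experiment bundles* between
steps: tar archives containing `otu_table.biom` (BIOM v1 JSON, dense, with
taxonomy embedded as observation metadata), and optionally
`sample_data.tsv`, `taxonomy.tsv`, `tree.nwk` and `refseq.fasta`. All members
are plain text. BIOM v2 (HDF5) input is detected by its magic bytes and
rejected with a version message rather than misread; RDP-pipeline and
Pyrotagger exports are recognised by name but deliberately unimplemented
(near-dead formats, no authoritative specification to parse against).

# Known limitations

* No variance-stabilizing model-based normalisation; the transforms here are
  the classical ones.
* No FDR procedures: the testing module is FWER-centric by design.
* No generalized or variance-adjusted UniFrac variants.
* The graphics layer computes layouts only; rendering aesthetics are the
  caller's concern.
* `betadiver` incidence indices follow their published formulas, some of
  which are similarities rather than dissimilarities; they are exposed
  as-is under their conventional one-letter names.
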