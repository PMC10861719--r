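---
title: "Methods: sex-stratified single-cell DE and Boolean network perturbation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-stratified single-cell DE and Boolean network perturbation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope and model

scDimorph analyses 2x2 genotype-by-sex single-cell RNA-seq designs — a
transgenic disease model (TG) against wildtype littermates (WT), males and
females profiled separately — the design used for early, pre-pathology
Alzheimer mouse cohorts. The pipeline runs:

1. **QC and normalization.** Cells with fewer than 200 or more than 2500
   detected features, or more than 5% mitochondrial counts, are removed
   (all comparisons strict, so a cell at exactly the boundary is kept).
   Normalization is a centered log-ratio: per cell,
   `y_g = ln(1 + x_g) - mean_g ln(1 + x_g)`, giving every cell a zero mean
   over genes. CLR is *not* invariant to a library-size multiplier; only
   the mean-zero contract is guaranteed and tested.
2. **Clustering.** The top 2500 genes by standardized variance (gene
   variance over a robust local-linear loess mean-variance trend) are
   z-scored, clipped at ±10 and embedded with a 10-component PCA. A
   shared-nearest-neighbor graph (Jaccard similarity of k = 20 Euclidean
   neighborhoods, self excluded, weights below 1/15 pruned) is partitioned
   with Louvain modularity over a resolution grid (0.2–2.0, step 0.2); the
   partition with the largest mean silhouette width in PC space wins, ties
   going to fewer clusters. Clusters are annotated by hypergeometric
   enrichment of marker gene sets among cluster-vs-rest upregulated genes
   (one-sided rank-sum, Bonferroni q < 0.05, mean difference > 0.25).
3. **Differential expression.** Within each (cell type, sex) stratum, and
   across all cells per sex, each gene is tested with a Poisson GLM
   `log mu = b0 + b1*TG + ln(total counts per cell)`, a likelihood-ratio
   test of `b1 = 0` against chi-square with 1 df, and Bonferroni
   adjustment over the genes tested in the stratum. `logFC` is the natural
   log coefficient `b1`. Genes detected in fewer than 3 cells of a stratum
   are skipped.
4. **Sex-pattern classification.** A gene is *neutral* when q < 0.05 in
   both sexes with a shared logFC sign, *dimorphic* with opposite signs,
   *male/female-specific* when q < 0.05 in one sex while the other sex has
   q > 0.5 (the wide buffer excludes near-significant genes), otherwise
   *unclassified*. The rules partition every tested gene.
5. **Over-representation analysis.** One-sided hypergeometric upper tail
   per gene set, universe defaulting to the union of the collection's
   sets, BH adjustment per DEG class, set sizes 10–500, gene ratio
   `k / N` with `N` the DEGs mapped to the universe. Classes with fewer
   than 3 mapped genes are skipped.
6. **GRN inference.** DE results of one stratum are Booleanized: TG state
   UP/DOWN for significant genes by logFC sign, WT the mirror. A directed
   prior network (activation / inhibition / unknown signs, curated
   regulatory categories) restricted to DEG nodes is pruned by a genetic
   algorithm; unknown signs are first resolved to the sign that makes the
   edge consistent with the phenotype states (matching states imply
   activation, opposite states inhibition; edges touching an UNCHANGED
   node stay unresolved and uninformative).
7. **Perturbation ranking.** On the TG network, each regulator is clamped
   to its WT state and the signed Boolean dynamics iterate synchronously:
   a node takes the sign-weighted majority of its regulators' states;
   tied nonzero majorities keep the TG state and are reported as
   conflicts; a missing fixed point within `2n` rounds flags the moving
   nodes as oscillating. The score is the number of downstream
   disease-state genes whose post-perturbation state equals WT.

## Choices the sources left open

- **GA objective.** The differential-GRN method the workflow follows names
  a genetic algorithm but not its objective. We use
  `fitness = n_consistent + n_covered_DEG_nodes - lambda * n_inconsistent`
  (lambda = 1): the consistency term mirrors "remove incompatible
  interactions", the coverage term rewards explaining DEGs, and
  uninformative edges contribute nothing so hub regulators stay
  connectable without rewarding padding. Tournament selection (size 3),
  uniform crossover (0.8), per-bit mutation (0.02), elitism (2),
  population 200, 300 generations — sized for priors up to ~200 edges;
  elitism makes the best fitness non-decreasing.
- **Propagation semantics.** Only the score's meaning is published
  ("downstream genes reverted toward control"). We chose synchronous
  updates, sign-weighted majority and conservative conflict handling
  (keep the disease state), so conflicted or oscillating nodes are never
  counted as revertible; an exact brute-force oracle reimplements the
  same semantics independently and must agree on every network.
- **Null-model deviance.** `stats::glm.fit` reports a null deviance that
  ignores the offset, so the null (intercept + offset) model is refitted
  explicitly; the LRT then matches the closed-form two-group deviance
  `2[T_A ln(r_A/r) + T_B ln(r_B/r)]` to 1e-8, which the tests verify
  against an independent oracle.
- **logFC scale.** The log base of the published fold changes is not
  stated; simulator and DE module use natural logs consistently.
  Classification depends only on sign and q, so the choice is
  inconsequential downstream.
- **Bonferroni family** is the set of genes tested within a stratum;
  pathway q values use BH, the convention of the enrichment tool the
  workflow names. The ORA universe is the union of the collection's sets
  (tool default), switchable to the measured genes.
- **Integration.** Anchor-based dataset integration is replaced by plain
  concatenation of arms: the DE model conditions on arm labels, so
  integration is not load-bearing for any quantity this package reports.
- **Variance trend.** The mean-variance trend uses degree-1 robust loess:
  a local-quadratic fit overshoots at the mean boundary and can absorb a
  genuinely variable gene into its own trend value.
- **Silhouette space.** Silhouettes are computed in PC space with
  Euclidean distance (the sources are silent on the space); the
  cluster-number search is a resolution grid rather than an explicit k
  sweep.
- **Config format.** Pipeline configs are JSON (no YAML parser among the
  supported dependencies); the format is equally diffable and the CLI
  overrides individual keys.

## The synthetic world

`simulate_bundle()` is the stated world for end-to-end testing: one
endothelial-like cell type, 300 cells per (genotype, sex) arm, 1000 genes,
lognormal size factors (sigma 0.3), 5% mitochondrial genes with 5% of
cells pushed above the mito QC threshold, and a 40-node / 60-edge acyclic
signed prior network (25% inhibition, 20% of signs masked as unknown)
over a random gene subset. The disease state is a single root-regulator
flip propagated along the true signs; every affected network gene gets a
male-specific planted logFC of ±1.0 aligned with its Boolean state, plus
a few neutral, female-specific and dimorphic genes outside the network.
Counts are Poisson with mean
`size_factor * exp(base + shifts + logFC_arm)` — deliberately the DE
model's own law first (an optional gamma overdispersion exists but
defaults off).

Two generator choices deserve justification. First, the transcriptome is
kept at 1000 genes: with only a few hundred genes, a few dozen strong
DEGs shift total per-cell counts enough that the library-size offset
induces spurious counter-regulation of every null gene — a composition
artifact real Drop-seq data (thousands of detected genes) does not show
at this planted effect size. Second, each cell type carries a disjoint
block of 10 marker genes with a +2 natural-log baseline shift; without a
cell-type-dependent mean component, cell types would be statistically
indistinguishable and clustering untestable.

A green test on this world establishes that the pipeline recovers planted
effects under its own model assumptions with realistic library-size and
mitochondrial variation. It does not establish robustness to ambient RNA,
doublets, batch chemistry, overdispersed counts, or gene-gene
co-expression beyond the planted network — none of which are simulated.

## Acceptance properties

The study's printed DEG lists, network figures and perturbation scores
depend on unreleased raw data and a proprietary interaction database, so
acceptance is property-based (see `tests/testthat/test-acceptance.R`):
exact agreement of the perturbation engine with a brute-force oracle on
100 random networks; GA optimality against exhaustive search on 12-edge
priors (>= 95% of 50 runs, never above the optimum); recovery of the
planted root regulator at rank 1 in >= 90% of 20 end-to-end runs;
per-class sensitivity >= 0.8 for the four sex patterns with null calls
below 5%; the closed-form Poisson deviance (worked value 3.398) to 1e-8;
hypergeometric exactness to 1e-12; the published per-gene statistics for
B2m (endothelial), Egr1 (astrocytes), mt-Rnr2 (neurons) and endothelial
Egr1 classifying as printed; and 3-cluster recovery with ARI >= 0.9 in
>= 9/10 seeds. The package carries no numeric acceptance targets, so
`scripts/acceptance.R` reports an empty object after a seeded smoke run.

## Known limitations

- The Poisson DE model ignores overdispersion; the MAST-style
  confirmatory analysis of the original workflow is out of scope.
- Cyclic priors are handled by bounded synchronous iteration with
  oscillation flags, not attractor enumeration.
- Sample-level replication (mice) is not modeled: cells are treated as
  exchangeable within arms, as in the underlying workflow.
- The silhouette selection is only as good as the resolution grid; very
  fine substructure may require a custom grid.
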