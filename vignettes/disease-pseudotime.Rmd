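---
title: "Staging disease progression from bulk transcriptomes with principal trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging disease progression from bulk transcriptomes with principal trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudostage)
```

## The problem

Cross-sectional bulk RNA-seq of postmortem brain tissue samples patients at
every stage of a slowly progressing disease, but each person is observed
once. If the transcriptome changes gradually and reproducibly with
progression, the cohort as a whole traces out a low-dimensional manifold in
gene-expression space, and each sample's position along that manifold is an
estimate of its *disease pseudotime* — a molecular stage that is finer than
any categorical diagnosis. Where the manifold forks, the forks are
candidate progression *subtypes* (branches). `pseudostage` implements this
staging strategy end to end: manifold learning with a tree constraint,
geodesic pseudotime and branch assignment, the downstream staging
statistics, and a synthetic-cohort generator with full ground truth so that
every step can be tested for recovery of known structure.

## The model

Let `x_i ∈ R^G` be the (log-scale, gene-centered) expression profile of
sample `i = 1..N`. We learn simultaneously a latent embedding
`z_i ∈ R^d` (default `d = 2`), cluster centers `y_k ∈ R^d` that lie on a
spanning tree, and an orthonormal inverse map `W ∈ R^{G×d}`, by minimizing

```
J = Σ_i ||x_i − W z_i||²
  + (λ/2) Σ_{k,k'} b_{kk'} ||W y_k − W y_k'||²
  + γ [ Σ_{i,k} r_{ik} ||z_i − y_k||² + σ r_{ik} log r_{ik} ]
```

subject to `B = (b_{kk'})` being a spanning tree over the centers,
`WᵀW = I`, and each row of the soft-assignment matrix `R` lying on the
probability simplex. The first term asks the latent embedding to reconstruct
the data through `W`; the second pulls the tree taut (its edges are scored
by the same geometry as the data, and since `WᵀW = I` the term reduces to
latent-space edge lengths); the third is an entropy-regularized soft
k-means coupling samples to centers, with the `0·log 0 = 0` convention.

### Exact block-coordinate descent

Every block has a closed-form exact minimizer, so a sweep can never increase
`J` — the package's optimizer tests assert this property on random states
and on whole traces:

* `R`: row-softmax of `−||z_i − y_k||²/σ` (computed with a row-max shift);
* `B`: the minimum spanning tree of the complete graph on centers under
  squared Euclidean weights (Prim's algorithm; ties broken toward lower
  vertex indices so fits are reproducible);
* `Y`: the solution of the symmetric positive-definite system
  `Y(λL + γΓ) = γZR`, where `L` is the tree Laplacian and
  `Γ = diag(Rᵀ1)`;
* `Z`: `(WᵀX + γYRᵀ)/(1 + γ)`;
* `W`: the orthogonal-Procrustes solution `UVᵀ` from the thin SVD of
  `XZᵀ` — an exact Stiefel-constrained minimizer of the reconstruction
  term (the other terms do not depend on `W` once `WᵀW = I`).

Sweeps run in the fixed order (R, B, Y, Z, W); any order is monotone, one
is fixed for reproducibility. Initialization: gene-wise centering (the
objective is translation-sensitive; no variance scaling), `W` from the
top-`d` left singular vectors with deterministic sign fixing, `Z = WᵀX`,
centers from a seeded k-means, then `R` and `B` by their own updates.
Convergence is declared when the relative objective change drops below
`tol` (default `1e-5`, at most 100 sweeps).

### Hyperparameters

| parameter | default | role |
|---|---|---|
| `d` | 2 | latent dimension; the tree is embedded in the plane |
| `K` | `N` | number of centers (one per sample) |
| `lambda` | `5N` | tree smoothness; larger values contract the tree |
| `gamma` | 10 | strength of the sample–center coupling |
| `sigma` | `1e-3` | entropy bandwidth; small values give near-hard assignment |
| `tol` | `1e-5` | relative objective stopping tolerance |

`K = N` follows the reference convention for this family of algorithms.
We deliberately did not adopt the `K ≈ 2√N` economy sometimes used for very
large cohorts: with few centers the fitted tree contracts well inside the
data cloud, a large fraction of samples project onto the two leaf vertices,
and their pseudotimes tie exactly at 0 or 1. Those ties both cap rank-based
recovery and make strict quantile rules (such as the resistant-control
definition below) degenerate. With one center per sample the projection is
essentially injective and the pseudotime distribution is continuous.

## From tree to stages

The fitted `B` is realized geometrically: vertices at the centers, edges
weighted by Euclidean length. *Branches* are maximal paths whose interior
vertices have degree 2 (the tree is cut at every vertex of degree ≠ 2),
numbered by their smallest vertex index. Each sample is projected to its
closest point over all edges (clamped orthogonal projection; ties to the
lowest edge id), inherits the branch of that edge, and receives a geodesic
distance from the *root*, min–max scaled to `[0, 1]` per fit (per-cohort
scaling, so pseudotimes are comparable within a study, not across studies).

The root is constrained to one of the two endpoints of the maximum-diameter
leaf-to-leaf path. Which endpoint is the "early" one cannot be decided by
geometry alone; when per-sample orientation labels are available (case
indicators), each sample is attached to the nearer endpoint and the
endpoint with the lower case fraction becomes the root, otherwise the
smaller vertex index is used, and `root_override` bypasses the rule. Note
that geodesics use plain Euclidean edge lengths — a distance along the tree
— not the squared weights used inside the MST step, which belong to the
objective.

Stability is assessed by leave-one-out refitting: drop one sample, refit
with identical parameters, restage, and record the absolute Pearson
correlation with the full-fit pseudotimes over the shared samples.

## Staging statistics

* **Case/control**: logistic regression of diagnosis on pseudotime, Wald
  test (`stats::glm`).
* **Ordinal neuropathology / cognitive scores**: proportional-odds model
  `P(Y ≤ j) = plogis(θ_j − βt)` (`MASS::polr`), likelihood-ratio test of
  `β = 0`. With two observed levels the model *is* binary logistic and is
  fitted as such — the package treats this collapse exactly.
* **Gene-set correlation shift**: each gene's Spearman correlation with
  pseudotime (average ranks at ties); a set's shift against the background
  of all other analyzed genes is tested with a two-group linear model.
* **Cell-type trajectories**: each marker gene is smoothed along
  pseudotime with a cubic smoothing spline tuned to 3 effective degrees of
  freedom (`stats::smooth.spline`), min–max normalized to `[0, 1]`
  (normalize-then-average, following the order in which the procedure is
  usually described; constant fits map to 0.5 to avoid 0/0), averaged
  within the marker set, and the set average is regressed on pseudotime.
* **Branch-specific differential expression**: one-way ANOVA across
  branches, then for every non-reference branch a Tukey
  honest-significant-difference contrast against the reference branch —
  the branch with the highest control fraction (ties: larger branch, then
  smaller id). The HSD p comes from the studentized-range distribution
  with (number of branches, N − branches) parameters (`stats::ptukey`).
  Benjamini–Hochberg correction is applied within each branch contrast
  across genes (the discovery family actually reported); a global-BH flag
  is available. Note the per-contrast HSD p is conservative by design —
  the exactly calibrated quantity is the familywise minimum over all
  pairwise contrasts, which the calibration tests check.
* **Enrichment**: one-sided Fisher/hypergeometric tests of query gene
  lists against user-supplied GMT collections over the analyzed-gene
  universe, BH across sets; odds ratios are the sample `ad/bc` with a 0.5
  continuity correction for display only when a margin cell is zero.
* **Biclustering**: genes are z-scored across samples (constant genes
  flagged and zeroed), averaged within branch, and the gene × branch
  matrix is clustered hierarchically on both axes (complete linkage,
  Euclidean distance); gene clusters come from cutting the row dendrogram
  (default 6 clusters — an assumption, configurable).
* **Resistant controls**: controls whose pseudotime lies strictly above
  the 0.8 type-7 quantile of *all* pseudotimes (the top quintile).
  Type 7 — linear interpolation — is fixed and documented because "top
  quintile" is ambiguous at ties. Their differential expression against
  all other samples (per-gene pooled t-tests, BH) is then intersected
  with branch-derived or planted gene clusters via one-sided Fisher
  overlap tests and the UpSet exclusive-intersection decomposition.

"FDR" always means Benjamini–Hochberg in this package. Gene filtering
before fitting offers a differential-expression filter (per-gene two-group
linear-model t-tests on log-CPM at FDR 0.10 — the threshold is exposed
because reasonable analyses also use 0.05) and a high-variance filter;
counts are filtered by the CPM > 1 in ≥ 50% of samples prevalence rule and
log2(CPM + 1) transformed. The package deliberately replaces heavier
normalization (conditional quantile normalization, moderated tests) with
these unmoderated equivalents: the synthetic cohorts have no GC/length
artifacts for them to correct.

## The synthetic-cohort generator

The generator produces what the analysis assumes, plus the truth needed to
score recovery:

* a small planar tree (`path`, `y`, `double_y`); the default `y` has a
  trunk of length 7 and fork arms of length 5 — with exactly equal arms
  the maximum-diameter path is ambiguous by symmetry and the root rule
  becomes ill-posed, and a longer shared trunk is also the realistic
  disease geometry;
* latent positions uniform by arc length; true pseudotime is the geodesic
  from the root min–max scaled (so 0 and 1 are attained exactly); true
  branches from the degree-≠2 decomposition;
* expression in two modes. `linear_gaussian` (default):
  `x_i = s·W_true z_i + f_g(t_i, branch_i) + ε`, `W_true` with orthonormal
  columns, `s = 10`, `ε ~ N(0, 1)` — per-gene trajectory signal is then
  weaker than noise (sd ≈ 0.6 at 500 genes) while the aggregate planar
  signal is strong, which is the regime that makes manifold learning both
  necessary and possible. Every gene carries manifold loading in this
  mode; "flat" means no planted program on top. `negbin_counts`:
  negative-binomial counts around `exp(β0_g + f_g)` times a log-normal
  library size; there, flat genes are genuinely null after CPM
  normalization. Programs `f_g`: monotone logistic in true pseudotime
  (amplitude 2) for increasing/decreasing genes, branch-confined shifts
  (1.5) for branch-specific genes;
* labels monotone in stage: case status `P = plogis(−2 + 4t)`, a 4-level
  proportional-odds score with cutpoints (0.4, 1.0, 1.6) and slope 2, and
  an allele dosage `Binomial(2, plogis(−1 + t))`;
* marker sets built from the planted programs (decreasing genes as the
  "neuron" signature; increasing genes split into "microglia" and
  "astrocyte"), a 60-gene "GWAS" set drawn from the increasing genes, and
  optionally a resistant-control construction: 9 controls above the 0.8
  pseudotime quantile receive a +2 (log-scale) shift in a designated
  50-gene cluster. Resistant individuals are controls *by definition*
  (disease-free despite late-stage molecular state), so if the stochastic
  label draw leaves fewer than 9 eligible controls, high-stage cases are
  relabeled as controls before planting.

One master seed drives a named sub-stream per generator stage, so any stage
can be regenerated independently and all outputs are bit-identical under a
fixed seed.

**What passing tests do and do not show.** The generator realizes exactly
the assumptions of the method: a low-dimensional, tree-shaped, additive
signal with homoscedastic noise and labels that truly follow logistic /
proportional-odds models. Real brain transcriptomes add batch and
composition effects, cell-type proportion shifts, heteroscedastic and
correlated noise, and label models that are at best approximations;
recovery on these cohorts therefore demonstrates correctness of the
implementation, not expected field performance.

## Problem sizes and numerical choices

The packaged tests exercise: pseudotime recovery on 10 path cohorts of
N = 200 samples × 500 genes (|Spearman| ≥ 0.95 expected in ≥ 9/10), branch
recovery on 10 Y cohorts of N = 300 × 1000 (ARI ≥ 0.7 in ≥ 8/10), null
calibration with 500 permutation replicates per test, power at the default
planted effects (logistic slope 4, ordinal slope 2, GWAS shift, 1.5-sd
branch programs), leave-one-out stability at N = 60, and exhaustive
combinatorial oracles (all 1296 labelled spanning trees on six centers;
hypergeometric enumeration over universes up to 40). These sizes were
chosen as the smallest at which the statistical claims are comfortably
testable.

Degenerate inputs are handled by documented rules rather than failures
wherever a convention exists: constant genes are dropped from t-test
selections (warning), map to 0.5 in trajectory normalization and to zero
rows in branch means; zero-length tree edges are treated as points;
zero within-branch variance uses p = 0/1 by whether the contrasted means
differ; samples projecting exactly onto a fork take the smallest incident
branch id; an empty resistant set is a warning, not an error. Separation
in logistic/ordinal fits is an explicit error, since the MLE does not
exist. Ties in the MST and in edge projection break toward lower indices.

## Limitations

Pseudotime is identified only up to the root choice (the orientation rule
needs labels or an override), and only up to monotone re-parameterization —
it is a molecular ordering, not calendar time. The maximum-diameter root
rule assumes the earliest samples sit at one end of the longest path; a
disease whose controls concentrate mid-tree would need `root_override`.
Branch counts depend on the fitted tree's degree structure and can split a
true branch in two near a noisy fork. The staging associations treat
pseudotime as fixed — uncertainty from the manifold fit is not propagated.
Out of scope by design: read alignment and quantification, conditional
quantile normalization, genome-wide single-variant association, and
comparisons to alternative embeddings.
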