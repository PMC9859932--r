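---
title: "Methods: cascade algebra, network inference and class comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cascade algebra, network inference and class comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellcascades)
```

## Overview

`cellcascades` treats a cellular identity as a *structure*, not a point in
expression space: the set of cascades (one- or two-gene sets with a
distinguished dependent gene) observable for a cell or a cell class. This
vignette documents the model and its assumptions, the tunable parameters and
their defaults, the numerical choices made where several were defensible,
what the synthetic generator does and does not emulate, and known
limitations.

## The cascade algebra

A cascade `{gx, gy}_gx` states that `gx` depends on `gy`; `{gx}_gx` encodes
the vertex `gx`. Equality requires equal member sets *and* equal dependent
genes, so the two orientations of an edge are distinct objects until
`to_undirected()` merges them. A complete possessed-cascade set contains
every gene's singleton plus one pair per observed dependency, which gives
the bookkeeping identity `|C| = |V| + |E|` used throughout.

Each cascade carries a three-element commutative semiring on
`members ∪ {ε}`, where `ε` is a reserved sentinel for the exogenous
environment (never admissible as a gene symbol; never stored in cascade
sets, whose `ε`-edges are implied). Addition behaves as a minimum for the
order *dependent gene < other member < ε* and multiplication is a truncated
accumulation with the dependent gene neutral and `ε` absorbing. The coding
map (dependent ↦ 0, other ↦ 1, ε ↦ ∞) is then a homomorphism onto
`({0, 1, ∞}, min, ⊙)`.

One numerical convention deserves a note: the numeric multiplication is
fixed as *truncated* tropical addition, `1 ⊙ 1 = ∞`, with `0` neutral and
`∞` absorbing. This is the unique choice that closes `{0, 1, ∞}` under the
operation while keeping the coding map a homomorphism — the product of the
two non-dependent carrier elements must map to `∞` because their semiring
product is `ε`. The test suite verifies every axiom and the homomorphism by
exhaustive enumeration of all carriers (35 triple checks), so this is
enforced, not assumed. Cascades only ever have one or two members; other
cardinalities are rejected by the constructor rather than given improvised
semantics.

Discarding genes admits two implementations: the induced subgraph
(`restrict_induced()`, keep cascades whose members survive) and the quotient
construction (`restrict_quotient()`: a cascade whose dependent gene is
discarded collapses entirely; one with a kept dependent merely loses
discarded members). On complete possessed sets the two agree exactly — the
formal justification for treating ignored genes as environment — and the
suite checks this equality on 1,000 random (universe, oracle, subset)
instances with up to 8 genes, alongside functoriality of restriction and its
commutation with orientation removal.

## Eigen-cascade inference

The eigen-cascades of a cell class are estimated from the pooled class
expression matrix by a **PC-stable skeleton search**: start from the
complete graph over the vertex panel and delete an edge as soon as some
conditioning set (size `0..max_cond`, drawn from the current neighbors of
either endpoint) renders the pair conditionally independent at level
`alpha`. Design choices:

* **Stable variant.** Neighbor sets are frozen per level, removing the
  dependence on edge-visit order that makes plain PC unstable. Genes are
  processed lexicographically and conditioning sets in sorted combination
  order, so the output is deterministic and invariant to row and column
  order of the input.
* **Skeleton only.** Orientation is deliberately discarded (no
  v-structure/Meek phase): the comparison metric operates on undirected
  structures, where the presence or absence of an edge is the stable,
  interpretable signal.
* **Tests.** Continuous data use the Fisher-z test on partial correlations
  obtained from the inverse sub-correlation matrix
  (`z = atanh(r)·sqrt(n − |S| − 3)`, two-sided normal reference; with an
  empty conditioning set the plain correlation is used directly, which keeps
  the degenerate perfectly-correlated case well-defined). Discrete data use
  a stratified Pearson chi-square pooled over conditioning strata, skipping
  (and counting) strata with any expected count below 5, the classical
  floor. Both are calibrated: under the null at `n = 10,000` their
  rejection rate at `α = 0.05` is within `0.05 ± 0.02` over 1,000
  replicates in the suite.
* **Binning.** The chi-square path needs discrete data. Columns with at
  most 5 distinct values are treated as categorical as-is; continuous
  columns are split at their median. Median-splitting already-binary data
  can degenerate to a single level, which is why discrete columns are
  passed through unchanged.

Defaults `alpha = 0.01`, `max_cond = 3`, Fisher-z, and a 30-cell class
floor. `alpha` doubles as the operational meaning of the "sufficient
proportion of cells carries the edge" requirement: pooling cells weakens a
dependency held only by a sub-population, and whether the pooled signal
survives is exactly the pooled test at `alpha`. Note the flip side: a class
formed of two equal halves, one with a strong edge and one without, still
shows a pooled correlation of roughly half the original, which a large
enough class will detect. Containment of a sub-population's edge in the
pooled structure is therefore a property of weak effects or moderate class
sizes, not a theorem; we document it rather than "fix" it.

## Comparing cell classes

The single-cell structural distance is the Hamming pseudo-metric
(symmetric-difference cardinality of cascade sets). It is exposed only for
externally supplied per-cell cascade sets (e.g. synthetic ground truth): a
network cannot be inferred from one cell's observation, so the package does
not pretend to estimate it.

Cell classes are compared with the asymmetric

\[ d^*(a, b) = 1 - \frac{|a \cap b|}{|a|} \]

on unoriented eigen-cascade sets. `d* = 0` exactly when `a ⊆ b`; the
denominator `|a| = |V| + |E|` is never zero because every vertex contributes
its singleton. `d*` is *not* a metric — it is asymmetric by design, and
simple finite counterexamples defeat the triangle inequality (take
`a = V ∪ {e1}`, `b = V ∪ {e1, e2}`, `c = V ∪ {e2}`), so the tests assert
only identity, bounds, asymmetry and subset-zero, never the triangle
property.

`compare_classes()` implements the three annotation modes (inference /
labeling / estimation differ only in which side is centered) and groups
compared classes onto rings of equal value. Two conventions:

* **Ring resolution.** Values are rounded to 4 decimals before grouping;
  with panels of tens of genes, distinct structural differences differ in
  the third decimal at most, so this merges only numerically identical
  values.
* **Ties.** All co-minimal classes are reported as the assignment,
  lexicographically ordered — never an arbitrary single winner.

## Feature selection

* **Factor analysis.** Variables with MSA `< 0.6` are dropped (re-applied on
  every refit, the conservative reading of an iterative workflow; a flag
  disables re-application), the factor count is set by Horn parallel
  analysis (100 independent column permutations, 95th percentile, leading-run
  counting), extraction is minimum-residual (unweighted least squares on the
  off-diagonal residuals, optimizing uniquenesses in `[0.001, 1]`), and the
  rotation is oblique quartimin via the gradient-projection algorithm —
  latent biological factors have no reason to be orthogonal. Factors are
  eliminated one per iteration (the one whose largest absolute loading is
  smallest) until every factor carries a loading of at least 0.5;
  communalities come from the unrotated solution so
  `communality + uniqueness = 1` holds exactly. Genes with communality
  `> 0.5` become network vertices.
* **Boosted trees.** The gradient-boosted selector (xgboost, `gbtree`, L1/L2
  regularization) runs in a grouped stratified k-fold: whole groups
  (subclasses) stay within one fold, so importance must reflect features
  shared across subclasses, with classes balanced beforehand by random
  undersampling to the smallest class. Each fold trains with early stopping
  on the held-out fold (10 rounds patience) and feature importance is read
  from the model at the *best* iteration — the model validation actually
  selects — which keeps pure-noise features out of the stable set. The
  selection rule is strict: a gene survives only with positive importance in
  *every* fold. A small optional hyperparameter grid (learning rate,
  leaves, L1/L2) is scored by mean validation log-loss.
* **Metrics.** One-versus-rest ROC-AUC (exact rank formula) and average
  precision (step-sum), macro-averaged AUC and micro-averaged AP, matching
  the usual multiclass evaluation conventions.

## Cell-class formation

k-means runs on regression-method factor scores for `k` in 2–15 with 10
restarts per `k`; the chosen `k` maximizes the mean silhouette coefficient
(Euclidean distance), with the smaller `k` winning ties (parsimony). The SD
of the silhouette, the entropy of the cluster-size distribution (natural
log; maximal `ln k` iff sizes are equal) and the inertia elbow are reported
as diagnostics but never used for selection — they exist to flag imbalance,
not to override the silhouette. Partition agreement is quantified by ARI and
AMI (expected MI under the fixed-margin hypergeometric model,
arithmetic-mean normalization).

## The synthetic generator

Ground truth is a linear-Gaussian structural model: an Erdős–Rényi DAG over
a random topological order, edge weights uniform in `±[0.5, 1.5]`, unit
exogenous Gaussian noise per gene — the environment realized as independent
exogenous parents. The sampled covariance converges to the closed form
`(I−W)⁻ᵀ(I−W)⁻¹σ²`, which the suite checks entrywise. A Bernoulli/logistic
mode mirrors the discrete test path, and a separate block-loading generator
drives the factor-analysis and clustering tests.

What it deliberately does **not** emulate: scRNA-seq count noise (dropout,
library-size variation, negative-binomial dispersion), batch effects, or
non-linear regulation. Passing tests therefore demonstrate that the
machinery recovers structure when the dependence model holds on normalized
values — not that any particular real dataset satisfies it.

Benchmark conditions used by the tests and the acceptance script (chosen as
representative desk-scale studies): 6-gene networks with edge probability
0.4; 5,000 cells for structure recovery (20 seeds, mean edge-F1 ≥ 0.9);
1,000 cells per class for annotation (3 reference + 3 query classes, 20
replicates); edit distances `k = 0..3` with 20 replicates for the
d*-monotonicity check; 500×20 block designs for factor analysis. Two
generation conventions matter for interpretability of these benchmarks:
perturbation edits never touch the same gene pair twice (so the skeleton
Hamming distance equals the edit count exactly), and multi-class studies
resample their ground-truth networks until skeletons are pairwise distinct
and *non-nested* — if one true skeleton contains another, the smaller
class's `d*` to the superset reference is exactly 0 and the "correct"
assignment is ambiguous by construction rather than by estimation error.

## Limitations

* The PC skeleton inherits the faithfulness assumption; near-cancelling
  paths can hide edges at any sample size.
* `d*` comparisons between classes of very different structural richness
  are hard to interpret: a class whose panel-restricted eigen-cascades are
  nearly vertex-only is "contained" in almost anything.
* Pooled-class inference blurs sub-population structure (see above); when
  classes are suspected to be mixtures, compare at finer partitions.
* The quartimin rotation is a local optimizer started from the identity; on
  clean block structure this is reliably the dominant solution, but heavily
  cross-loaded designs may admit alternative rotations of equal criterion
  value.
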