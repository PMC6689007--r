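---
title: "Signaling entropy, potency states and cell-density landscapes"
author: "scPotency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signaling entropy, potency states and cell-density landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scPotency)
```

## The model

scPotency estimates the differentiation potency of a single cell from its
transcriptome and a protein-protein interaction (PPI) network, without
marker genes. The idea: a cell's normalized expression profile
$x$ (strictly positive, aligned to the network's genes) weights each network
edge $(i, j)$ by $w_{ij} \propto x_i x_j$, interpreted as an interaction
probability. Row-normalizing the weights yields a random walk on the network
with transition matrix

$$ p_{ij} = \frac{x_j}{(Ax)_i}, \qquad j \in N(i), $$

where $A$ is the binary, symmetric, zero-diagonal adjacency matrix and
$N(i)$ the neighbors of gene $i$. The walk's stationary distribution has the
closed form

$$ \pi_i = \frac{x_i (Ax)_i}{x^\top A x}, $$

which satisfies detailed balance $\pi_i p_{ij} = \pi_j p_{ji}$ (the walk is
reversible), and the **signaling entropy rate** is

$$ Sr(x) = -\sum_i \pi_i \sum_{j \in N(i)} p_{ij} \log p_{ij} $$

in nats ($0 \log 0 := 0$, applied structurally by summing only over edges).
Pluripotent cells express promiscuously, spreading signaling flux evenly over
the network and driving $Sr$ up; committed cells concentrate flux in
lineage-specific modules, driving it down.

For a fixed topology, $Sr$ is maximized by the *maximal-entropy walk*

$$ P^{\max}_{ij} = \frac{A_{ij} v_j}{\lambda v_i}, $$

with $(\lambda, v)$ the dominant (Perron) eigenpair of $A$; its rate is
$\max Sr = \ln \lambda$ and its stationary distribution $\pi_i = v_i^2$. The
normalization constant is necessarily $\lambda$ — it is the unique value that
makes the rows sum to one — so it is fixed, not configurable. The
**normalized entropy rate**

$$ SR(x) = \frac{Sr(x)}{\ln \lambda} \in (0, 1] $$

is comparable across cells and attains 1 exactly when the weighted walk
coincides with the maximal-entropy walk, i.e. when $x \propto v$ (on a
$k$-regular graph, uniform $x$ suffices, because there $v$ is constant).

Because the Perron theory behind $\lambda$ and $v$ requires an irreducible
adjacency, the network is always reduced to its largest connected component
after intersection with the data's genes, and components of fewer than two
nodes are an error rather than a silent degenerate answer.

## Potency states

$SR$ is bounded in $(0, 1]$, so cells are compared on the base-2 logit scale
$y = \log_2(SR / (1 - SR))$ (the base is a convention for this scale only;
$SR$ itself is base-invariant as a ratio of two natural-log rates). A
one-dimensional Gaussian mixture with $K = 1 \ldots k_{\max}$ components is
fitted to the population's $y$ values and $K$ is selected by BIC, in the
convention $\mathrm{BIC} = -2\,\mathrm{loglik} + p \log n$, minimized —
algebraically the same selection as the maximizing convention used by mclust,
which performs the fits. Components are relabeled by ascending mean, so state
1 is the least and state $K$ the most potent; "high potency" always means the
state with the largest mean. Defaults: $k_{\max} = 6$ with unequal component
variances (the more general model; a shared-variance fit is available via
`varModel = "E"`). Fitting uses mclust's deterministic hierarchical
initialization, so results are identical run to run; the `seed` argument is
fixed anyway for any stochastic fallback.

## From states to landscapes

Cell *types* are inferred independently of potency: the HVG-reduced
expression matrix (genes with mean > 1 and sd > 1 on the log scale, strict
inequalities, sd with denominator $n - 1$) is embedded in 2-D by t-SNE over
30 initial principal components (perplexity 30, 1000 iterations), then
clustered with DBSCAN (eps = 5, minPts = 15). Noise points get the reserved
*peripheral* label 0. Because eps is scale-dependent on the embedding, any
externally supplied 2-D coordinates can be used instead of the built-in
t-SNE; this is a documented caveat, not a hidden assumption. Cluster labels
are renumbered by descending size so outputs are order-stable; for clusters
of exactly equal size the numbering follows first occurrence, so only the
partition (not the label numbers) is guaranteed under input permutation.

A **cell-state** is a (potency state, cluster) pair with at least `minCells`
cells (default 5 — the threshold is a qualification rule, chosen small enough
not to suppress genuine small states on fixture-scale data; pairs below it
are still tabulated). Peripheral cells are tabulated in their own column but
never qualify. Per potency state, a Gaussian-kernel 2-D density
("cell-density elevation map") is estimated on a shared 100 x 100 lattice
spanning the bounding box of *all* cells, with Scott's-rule bandwidths per
subset, and renormalized to integrate to exactly 1 — the shared extent is
what makes surfaces of different potency states comparable as elevations.

## Root and trajectories

The **root** is the cell of maximal $SR$ (ties to the smallest index). For
trajectories we use diffusion maps: a symmetric kNN graph (k = 30) on
Euclidean distances over the HVG expression (expression, not the t-SNE
coordinates, to avoid compounding embedding distortion); a Gaussian kernel
with per-cell bandwidth equal to the median distance to the k nearest
neighbors; density normalization with $\alpha = 1$ (kernel divided by the
outer product of its row sums), which removes first-order sampling-density
effects — with a fixed bandwidth, duplicating every cell leaves the
nontrivial spectrum unchanged, and the test suite asserts exactly that; then
row normalization and eigendecomposition of the conjugate symmetric
operator. The trivial eigenvalue-1 constant component is excluded, the top
`nDCs = 10` nontrivial eigenpairs retained, and components are normalized to
be orthonormal under the sampling measure with a deterministic sign
convention (largest-magnitude entry positive).

**Diffusion pseudotime** from root $r$ uses the spectral closed form over the
retained eigenpairs,

$$ \mathrm{dpt}(i) = \Big( \sum_\ell \big( \tfrac{\lambda_\ell}{1 -
\lambda_\ell} \big)^2 \, (\psi_\ell(i) - \psi_\ell(r))^2 \Big)^{1/2}, $$

equivalent in the truncated eigenspace to the matrix-inversion formulation
but numerically direct. It is zero at the root and symmetric as a pairwise
distance. Tips are the argmax of dpt globally and within each non-peripheral
cluster. Branch *assignment* (partitioning cells among branches) is out of
scope; only tips and pseudotime are produced.

## Signature statistics

* **Potency-associated differential expression**: per-gene OLS of normalized
  expression on the potency estimate (or a binary group), optionally
  adjusting for the two cell-cycle scores; two-sided t-test on the response
  coefficient; Bonferroni over genes actually tested. For within-cluster
  contrasts, where dropout confounds small differences, `dropZeros = TRUE`
  restricts each gene's fit to cells where it is expressed. "Expressed" needs
  a numeric rule on the normalized scale: entries at or below the `zero`
  baseline are treated as dropouts (0 by default; `log2(1.1)` is the natural
  baseline for the library normalization below, where a zero count maps to
  exactly that value).
* **Cell-cycle scores**: per-phase average of gene-wise z-scores across
  cells; zero-variance or absent signature genes are dropped with a count.
* **Signed signatures**: the top `nUp` upregulated plus top `nDn`
  downregulated significant genes (default 72 + 72), signs +1/-1, ties in t
  broken by gene id. A sample's score is the Pearson correlation between the
  sign vector and its expression over the signature genes — +1 on a matching
  profile, -1 on its negation, invariant to positive affine transforms.
* **Rank-based GSEA**: unweighted running statistic (+1/m at hits,
  -1/(N-m) at misses — the classic Kolmogorov-Smirnov form; rank-weighted
  variants are deliberately not the default since the scoring is purely
  rank-based), observed max ES, and a Monte-Carlo null from uniformly
  reshuffled rankings; NES = maxES / mean(null), p from a Gaussian upper
  tail fitted to the null maxima.
* **Monte-Carlo mean-difference test**: observed mean of a per-gene
  statistic over a gene set vs. same-size uniform draws; one-tailed
  $p = (r + 1)/(n_{MC} + 1)$.
* **Overlap enrichment**: 2 x 2 odds ratio with Haldane's 0.5 correction on
  zero cells and a one-tailed hypergeometric p.

## Preprocessing defaults

Droplet counts: keep cells detecting $\ge$ 1000 genes (raw count > 0) with a
mitochondrial count fraction strictly $<$ 0.05; remove mitochondrial genes;
recompute the total count $TRC_c$; with $maxC = \max_c TRC_c$ set

$$ LSC_{gc} = \log_2\!\big( RCM_{gc} \cdot maxC / TRC_c + 1.1 \big). $$

The 1.1 pseudocount keeps the matrix strictly positive (minimum
$\log_2 1.1$), as the entropy machinery requires, and back-transforming
conserves the rescaled library size exactly:
$\sum_g (2^{LSC} - 1.1) = maxC$ for every cell. The core nevertheless
validates positivity and rejects nonpositive entries rather than clipping —
explicit failure beats silent bias. FPKM matrices use $\log_2(x + 1)$.
Mitochondrial genes are identified by an "MT-" prefix by default, or an
explicit gene list; gene-id mapping is an optional user-supplied table, with
unmapped genes dropped and counted.

## What the synthetic generators emulate — and what they do not

All generators are pure functions of (parameters, seed).

* `simulateNetwork`: connected Erdos-Renyi or preferential-attachment
  topologies — a stand-in for a curated PPI network's connectivity, not its
  biology.
* `simulatePotencyPopulation` plants the structure the potency model
  assumes: each cell draws a latent potency $t \in (0,1)$ whose base-2 logit
  comes from an `nStates`-component Gaussian mixture (unit variances, means
  `separation` apart); expression is
  $(1 - t) \cdot (\text{state-specific module profile}) + t \cdot
  (\text{uniform profile})$, times lognormal noise. Higher $t$ spreads flux
  more evenly, so SR increases with $t$ by construction.
* `simulateBifurcation` plants a Y-shaped trajectory in profile space. The
  root vertex is a *shrunk Perron profile* $v^{0.95}$ of the accompanying
  network: on an irregular graph the SR-maximizing profile is $v$ itself
  (not the uniform profile), and the mild shrink keeps the root's SR
  strictly below 1 so its logit stays finite. The first cell is pinned
  noise-free at that vertex, making the planted maximal-potency root
  unambiguous. Cells are placed at stratified (jittered-grid) arclengths
  rather than i.i.d. uniform: with i.i.d. positions, near-duplicate
  arclengths make adjacent-cell order unidentifiable at any noise level,
  whereas the method's local-order recovery is exactly what the fixture is
  meant to probe. Default noise (sd 0.02 against vertex profile contrasts of
  order 10) is chosen for testability: diffusion pseudotime on the
  noise-free fixture is exactly monotone along every branch, so measured
  violations isolate the noise-versus-spacing trade-off.
* `simulateCounts10x` produces negative-binomial counts with Bernoulli
  dropout, an "MT-" gene block, and two planted boundary cells — one at
  exactly the minimum-genes threshold (must be kept: inclusive rule) and one
  at exactly the mitochondrial-fraction threshold (must be removed: strict
  rule).

None of these emulate real scRNA-Seq batch structure, ambient RNA, doublets,
UMI saturation, or realistic gene-gene correlation. Passing tests therefore
demonstrate that the algorithms recover what they are designed to recover
under their own model assumptions — not that those assumptions hold in any
particular tissue.

## Numerical choices

* Dominant eigenpair: power iteration on $A + I$ (the shift separates the
  Perron eigenvalue even on bipartite graphs, where $-\lambda$ is also an
  eigenvalue) from a deterministic all-ones start; residual tolerance
  $10^{-10}\lambda$ enforced post hoc.
* Entropy rate: computed without materializing $P$, via
  $\sum_j p_{ij} \log p_{ij} = (A(x \log x))_i / (Ax)_i - \log (Ax)_i$; one
  sparse matrix product serves all cells, so results are independent of cell
  order and chunking.
* Mixture selection: BIC per $K$ on unequal-variance fits; fit failures
  yield NA in the BIC table and are skipped.
* DBSCAN: core points need `minPts` neighbors within eps (self included);
  border points join their *nearest* core point, so the partition does not
  depend on input order.
* KDE: product Gaussian kernel, Scott's rule $\hat\sigma_d n^{-1/6}$ per
  axis per subset, grid renormalized to unit mass.
* Diffusion maps: eigenvalues numerically $\ge 1$ among the nontrivial
  components trigger a disconnected-kNN-graph warning (suggesting larger k).
* Degenerate inputs error loudly: nonpositive expression after network
  alignment (naming the cell and gene), constant responses, all-identical
  mixture inputs, empty network/gene-set intersections.

## Problem sizes

The test-suite and acceptance fixtures use networks of 10-200 genes,
populations of 60-300 cells, 20-50 seeded replicates per stochastic claim,
and Monte-Carlo depths of 99-1000 — sizes at which every oracle (dense
eigendecompositions, brute-force entropy sums, exhaustive KS checks) is
exact and fast, chosen so the full suite re-runs in well under CRAN-style
check budgets. The algorithms themselves are sparse and scale to
genome-sized networks (the per-cell cost is one sparse matrix-vector
product).

## Known limitations

* The PPI network is an input; results inherit its curation biases. The
  package ships no network.
* SR compresses near its upper bound; very-high-potency cells may differ by
  less than measurement noise on the logit scale.
* DBSCAN's eps is tied to the t-SNE output scale; reusing eps = 5 with a
  different embedding algorithm is not meaningful.
* Diffusion pseudotime assumes a connected kNN graph; disconnected
  populations need a larger k or per-component analysis.
* Branch assignment, doublet detection, batch correction, imputation and
  survival modelling are out of scope.
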