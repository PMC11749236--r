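---
title: "Methods: hierarchical protein systems and selective-pressure scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical protein systems and selective-pressure scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`hiersys` implements a two-stage analysis for tumor systems biology:

1. **Hierarchy construction.** A protein affinity graph — nodes with
   sequence-derived feature vectors, undirected edges with five
   association channels (physical evidence, mRNA co-expression, protein
   co-expression, sequence similarity, co-dependence) — is clustered into
   a multi-level tree of protein systems by a supervised
   linkage/density GNN in the Hi-LANDER family, extended with a
   message-passing encoder (MPGNN) that consumes edge features. Training
   is supervised by flattened GO classes; inference iterates
   *score → decode → aggregate* until clusters stop merging.
2. **Selective-pressure scoring.** Given the hierarchy and a nonnegative
   gene-level signal $y$ (corrected mutation counts, a meta-survival
   $z$ combination, perturbation amplitudes, or dependency scores), the
   model $y = Iw + Hv$, $w, v \ge 0$ is fit along a 500-value lasso path,
   each system is summarized by its maximal weight fraction $S(c)$, and
   significance is assessed by permuting the rows of the membership
   matrix $H$, with Benjamini–Hochberg control and a conventional
   FDR < 0.25 hotspot cutoff. Hotspots drive bottom-up pruning and
   Cytoscape export.

# Stage one: the clustering model

## Inputs and supervision

The level-0 graph $G_0 = \{V, E, X_V, X_E\}$ carries per-node features
(default width 1280 in production, the standard protein-language-model
embedding width; any width is accepted) and the five channel scores per
edge. Channel scores are taken as given and never rescaled on load;
normalization, if wanted, is a modeling choice, not an I/O side effect.

GO annotation is multi-label, so `flatten_go_labels()` reduces it to one
class per gene: terms outside a size window (default 10–500 genes) are
discarded, and each gene keeps its *smallest* surviving term — its most
specific usable annotation — with ties broken by term id. Genes with no
surviving term are excluded from supervision (they still participate in
message passing and inference).

Nodes are split 70:10:20 into train/validation/test by a seeded shuffle
(train and validation sizes are `round(n * ratio)`, test takes the rest).

## Architecture

* **Input.** Each node carries two feature blocks: a *mean* block and a
  *peak* block (equal at level 0). Each block is row-L2-normalized and the
  two are concatenated, then linearly projected to the hidden width. The
  normalization makes the geometry scale-free across levels, which is what
  lets one trained model score every level.
* **Message passing** (default 2 layers, hidden width 256). The message
  into node $i$ from neighbor $j$ is
  $\mathrm{ReLU}(W_m [h_i, h_j, e_{ij}] + b_m)$; messages are
  mean-aggregated and the node is updated by
  $\mathrm{ReLU}(W_u [h_i, \bar m_i] + b_u)$. Neighborless nodes update
  from their own state only. At level 0, $e_{ij}$ is the 5-channel vector;
  at levels $\ge 1$ the scalar KNN similarity is replicated across the
  five slots so the *same* trained transform applies. (The alternative —
  separate per-level edge transforms — leaves the upper-level path
  untrained, because training sees only level 0.)
* **Heads.** States are L2-normalized, then a logistic *linkage head*
  scores each edge from
  $[s_u, s_v, |s_u - s_v|, s_u \odot s_v, e_{uv}]$ and a tanh *density
  head* scores each node. Including $e_{uv}$ in the linkage head is a
  deliberate extension of the usual symmetric-pair featurization: without
  it the head cannot distinguish a weak from a strong edge between
  equally similar endpoints, and the learned rule would not transfer to
  the similarity-weighted edges of levels $\ge 1$, leaving the hierarchy
  stuck at one level.

## Training

Targets come from the labels: an edge's target is 1 iff its endpoints
share a class; a node's density target is the edge-weighted balance
$\sum_j s_{ij} a_{ij} / \sum_j s_{ij}$ with $a_{ij} = \pm 1$ for
same/different class and $s_{ij}$ the mean channel score (level 0) or
similarity weight. The loss is
$w_1 \cdot \mathrm{BCE}(\text{edge prob}) + w_2 \cdot \mathrm{MSE}(\text{density})$
with $w_1 = w_2 = 1$ (plain BCE rather than focal loss — simpler and
testable), restricted to the training-node induced subgraph so no label
information leaks through loss edges. Optimization is full-batch Adam
(default 200 epochs, step 0.05), seeded and fully deterministic;
gradients are analytic and are checked against finite differences in the
test suite. Validation pairwise-F is recorded every `eval_every` epochs
by decoding the *full* graph with the current parameters and restricting
the resulting partition to validation nodes — transductive evaluation;
the validation-induced subgraph alone is too sparse to decode at
realistic split sizes.

## Decoding and aggregation

`decode_level()` keeps, per node, at most one incident edge: the
highest-probability neighbor with probability $\ge p_\tau$ (default 0.5)
and density $\ge$ the node's own, ties to the smaller node id. Clusters
are connected components of kept edges — peak-seeking: links flow toward
local density peaks, so raising $p_\tau$ only removes links and can never
merge clusters. `aggregate_level()` makes one node per cluster (mean
feature = average of member mean features; peak feature = mean feature of
the member with maximal predicted density, ties to the smaller id) and
wires levels $\ge 1$ as mutual $k$-nearest neighbors under cosine
similarity on mean features ($k = 10$ default), with the similarity as
scalar edge weight. Systems are created only for clusters of size
$\ge 2$; singletons pass through unchanged and may join a system at a
later level. Iteration stops when nothing merges or at `max_levels`.

Why depth emerges at all: supervision is *coarser* than the finest
structure in the graph (GO classes are coarser than tight complexes).
Within a class, the strong-edge/high-similarity pairs are decoded first
into fine clusters; at the next level the aggregated nodes of the same
class are again mutually similar and carry similarity weights comparable
to the level-0 positives, so the same head keeps linking until clusters
are label-pure. A model supervised at the finest granularity terminates
after one level by construction.

## Evaluation

`pairwise_f()`, `bcubed_f()` and `nmi()` use the standard definitions;
NMI normalizes by the arithmetic mean of the two natural-log entropies.
Two conventions keep the metrics total: all-singleton vs all-singleton
compares as perfect (no pairs to get wrong), and NMI of two identical
partitions is 1 even in the degenerate one-cluster case (otherwise 0 when
both entropies vanish). `evaluate_hierarchy_level()` cuts the tree at a
level: each gene maps to its deepest ancestor with level $\le \ell$
(so a gene whose branch skips level $\ell$ exactly is still assigned the
system active there), and genes with no ancestor at or below $\ell$ stand
as singletons.

# Stage two: selective pressure

With $n$ genes and membership matrix $H$ (entry 1 iff the gene belongs to
the system's descendant gene set), the path solves, per $\lambda$,

$$\min_{w, v \ge 0} \tfrac{1}{2n}\lVert y - Iw - Hv\rVert^2
  + \lambda (\textstyle\sum w + \sum v).$$

The nonnegativity constraint reflects that $w, v$ model *positive*
selection pressure. The objective scaling fixes
$\lambda_{\max} = \max_j X_j^\top y / n$, at which the solution is exactly
zero; the grid is 500 log-spaced values down to
$\lambda_{\max} \cdot 10^{-3}$. Columns are *not* standardized: $H$ is
binary and standardizing would distort system-size semantics (exposed
nowhere as a default for exactly that reason). The solver is exact
cyclic coordinate descent with warm starts; the KKT residual is reported
per grid point and is ~$10^{-12}$ at the default tolerance ($10^{-9}$).

$S(c)$ is the maximum over the path of $v_c / (\sum v + \sum w)$, skipping
grid points with zero total weight; shares sum to one, so
$S(c) \in [0, 1]$. Significance: rows of $H$ are permuted as whole rows
(each system keeps its size and the nesting structure is preserved), the
full path and $S$ are recomputed per permutation, and
$p(c) = (1 + \#\{S_{\text{perm}}(c) \ge S_{\text{obs}}(c)\}) / (1 + n_{\text{perm}})$
— add-one so $p > 0$. BH follows; `significant` means $q$ below the
cutoff (0.25 by convention for this screen). Signed tracks (meta-z,
perturbation, dependency scores) default to an absolute-value transform;
rectification is explicit and recorded on the track.

Numerical choices worth knowing:

* Permutation-heavy runs accept a looser KKT tolerance ($10^{-4}$ in the
  packaged acceptance studies): the induced error in $S$ is ~$10^{-5}$,
  three orders below anything the $\ge$ comparison can feel, and it is
  the difference between minutes and an hour for $10^4$ path solves.
* An all-zero signal returns a valid, flagged all-zero path.
* Ties in $S$ count against significance (the $\ge$ is inclusive), which
  makes constant signals give $p = 1$ exactly.

## Behavior of the permutation null (read before designing simulations)

Two structural facts about $S$ matter when checking calibration and
power on synthetic data:

* **Atoms under nesting.** In a nested hierarchy a leaf system whose
  signal is absorbed by its parent can have $S = 0$ with positive
  probability; its permutation p-value is then exactly 1 (tie). Null
  p-values are therefore *conservative*, not uniform, in nested designs.
  Uniformity holds — and is tested — in a flat design with a continuous
  track, where exchangeability applies cleanly.
* **Argmax symmetry in flat designs.** In a flat design of $m$ sibling
  systems, each permutation hands some system $S = 1$ (the first path
  entrant), so every p-value has a floor near $1/m$ — which caps BH power
  at small $m$. Power studies therefore use a nested design, where
  permuted leaf columns are dominated by the larger parent columns and
  genuinely burdened leaves separate cleanly.

# The synthetic world

`simulate_dataset()` plants: balanced multi-level communities
(default 300 genes in 20 leaf clusters inside 5 super-clusters);
hierarchically Gaussian features (child mean = parent mean +
$N(0, 1.0^2)$ per dimension, gene = leaf mean + $N(0, 0.2^2)$; feature
width 32, a scaled stand-in for 1280) so deeper clusters are tighter,
mirroring the assumption that GO-coherent systems share embedding
similarity; channelized edges (within-leaf probability 0.9 with scores
$N(0.8, 0.1^2)$ clipped at 0; between 0.02 with $N(0.1, 0.1^2)$ — one
law for all five channels, since nothing dictates per-channel models);
flat labels equal to the planted cluster ids at `label_level` (default:
the *top* level, per the depth argument above); and burden tracks on
planted leaf systems — Poisson(base + effect) counts and
$N(\text{effect}, 1)$ z-scores.

What it does **not** emulate: real sequence composition (the hashed
embedder is a determinism device, not biology), heavy-tailed PPI degree
distributions, correlated channels, annotation noise and multi-label
overlap, or cohort-level survival structure. A green recovery test
establishes that the machinery learns and decodes planted structure
under its stated noise — not that it reproduces any published hierarchy.

# Known limitations

* Training is level-0 only (per the training contract); upper levels are
  scored by transfer through the shared, scale-free featurization. Deep
  (>3-level) hierarchies on synthetic data require the planted geometry
  to cooperate.
* The permutation test inherits the conservativeness described above;
  reported q-values for deeply nested, weakly loaded systems are honest
  but blunt.
* The pretrained embedding backend is a plug-in (`custom_backend()`);
  the package ships only the hashed stand-in, so production feature
  extraction happens outside the package.
* `read_ontology()` reconstructs levels as 1 + max child level; a file
  written with different level conventions round-trips structurally but
  not numerically.
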