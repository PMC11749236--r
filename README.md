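# hiersys

Hierarchical protein system discovery and selective-pressure scoring for
cancer systems biology.

Single-gene analyses miss selection pressure that is spread across a
pathway: many low-frequency mutations, or many small survival effects,
can add up on a coherent protein system while no individual gene looks
remarkable. `hiersys` is for researchers who want to (1) organize a
protein–protein affinity graph into a data-driven, multi-level tree of
protein systems and (2) ask which of those systems carry significant
gene-level burden — mutation counts, meta-survival z-scores, drug
perturbation or dependency scores.

## The method

**Stage 1 — hierarchy construction.** The input is an affinity graph
`G0 = {V, E, X_V, X_E}`: protein nodes with sequence-embedding features
`X_V` and edges carrying five association channels `X_E` (physical
evidence, mRNA co-expression, protein co-expression, sequence similarity,
co-dependence). A message-passing GNN, trained against flattened GO
classes, scores each edge with a linkage probability and each node with a
density. Decoding keeps, per node, its best edge toward a
higher-density neighbor above a threshold `p_tau`; connected components
of kept edges are clusters; clusters aggregate into the nodes of the next
level (mean + density-peak features, mutual-kNN cosine edges), and the
procedure iterates into a tree of systems over gene leaves. Agreement
with labels is measured by pairwise F, BCubed F, and NMI.

**Stage 2 — selective pressure.** For a nonnegative gene signal `y` and
the binary gene-by-system membership matrix `H`, solve along a
500-value lasso path

    min_{w,v >= 0}  1/(2n) ||y - I w - H v||^2 + lambda (sum w + sum v)

so systems (`v`) compete with individual genes (`w`) to explain the
signal. Each system gets `S(c) = max_lambda v_c / (sum v + sum w)`, a
permutation p-value from row-permuted `H` (10,000 permutations by
convention), and a Benjamini–Hochberg q-value; systems with `q < 0.25`
are clinical hotspots. Hotspots guide bottom-up pruning of the tree and
Cytoscape (SIF + attributes) export.

## Worked example

Everything below runs offline on the seeded synthetic generator (planted
20 leaf clusters inside 5 super-clusters over 300 genes, plus burden
tracks on 3 planted systems).

```r
library(hiersys)

d <- simulate_dataset(synthetic_spec(seed = 1))
cfg <- model_config(hidden_dim = 64, epochs = 150, learning_rate = 0.05,
                    seed = 1)
m <- train_model(d$graph, d$labels, split_nodes(d$graph$node_ids, seed = 1),
                 cfg)
h <- infer_hierarchy(d$graph, m)
h
#> <hierarchy> 300 genes, 22 systems, 2 levels

evaluate_hierarchy_level(h, d$truth$level1, 1)$nmi  # 0.957
evaluate_hierarchy_level(h, d$truth$level2, 2)$nmi  # 1.000
```

The inferred tree recovers the planted leaf clusters (NMI 0.96 against
the 20 planted level-1 communities) and the super-clusters exactly
(NMI 1.00 at level 2). For burden scoring:

```r
db <- simulate_dataset(synthetic_spec(n_genes = 480, branching = c(80, 20),
                                      planted_systems = 3, effect_size = 3,
                                      seed = 1))
res <- run_hisig(db$tracks$zscores, db$hierarchy, n_perm = 500, seed = 1)
head(res, 3)
#>   system_id n_genes         S           p          q significant
#>     (the 3 planted systems, q = 0.0665, significant = TRUE)
sum(res$significant)  # 3 -- exactly the planted systems
pruned <- prune_hierarchy(db$hierarchy, res$system_id[res$significant])
export_cytoscape(pruned, "tree.sif", "tree_attrs.tsv",
                 data.frame(id = res$system_id, S = res$S, q = res$q))
```

`q = 0.0665` is the minimum attainable at 500 permutations after BH over
100 systems at rank 3 (`(1/501) * 100 / 3`): the planted systems sit at
the permutation floor, and nothing else clears the FDR < 0.25 cutoff.

A command-line wrapper covers the same pipeline
(`simulate`, `embed`, `build-graph`, `train`, `infer`, `eval`, `hisig`,
`intersect`, `prune`, `export`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "hiersys.R", package = "hiersys"))')" \
  simulate --out data --seed 5
```

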