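chain4 <- function() {
  ids <- sprintf("n%d", 1:4)
  feats <- matrix(rnorm(8), 4, dimnames = list(ids, NULL))
  build_affinity_graph(
    as_edge_table(toy_edges(c("n1", "n2", "n3"), c("n2", "n3", "n4"), 0.5)),
    feats)
}

test_that("decode_level follows the peak-seeking rule (worked example)", {
  withr::local_seed(1)
  g <- chain4()
  sc <- linkage_scores(g, edge_prob = c(0.9, 0.4, 0.8),
                       node_density = c(n1 = 0.1, n2 = 0.5, n3 = 0.2,
                                        n4 = 0.6))
  part <- decode_level(g, sc, p_tau = 0.5)
  expect_equal(unname(part[sprintf("n%d", 1:4)]), c("n1", "n1", "n3", "n3"))
  expect_equal(nrow(attr(part, "kept_edges")), 2L)

  # threshold above every probability -> all singletons
  all_sing <- decode_level(g, sc, p_tau = 0.95)
  expect_equal(length(unique(all_sing)), 4L)

  # saturated probabilities + monotone densities on a path -> one cluster
  sc2 <- linkage_scores(g, rep(1, 3), c(n1 = .1, n2 = .2, n3 = .3, n4 = .4))
  expect_equal(length(unique(decode_level(g, sc2, 0.5))), 1L)
})

test_that("raising p_tau never merges clusters (kept-edge monotonicity)", {
  withr::local_seed(33)
  for (case in 1:20) {
    n <- 12L
    ids <- sprintf("n%02d", seq_len(n))
    pairs <- t(combn(ids, 2))
    keep <- runif(nrow(pairs)) < 0.3
    g <- build_affinity_graph(
      as_edge_table(toy_edges(pairs[keep, 1], pairs[keep, 2], 0.5)),
      matrix(rnorm(2 * n), n, dimnames = list(ids, NULL)))
    prob <- runif(nrow(g$edges))
    dens <- stats::setNames(runif(n), ids)
    taus <- sort(runif(4))
    parts <- lapply(taus, function(tau)
      decode_level(g, linkage_scores(g, prob, dens), tau))
    for (k in seq_along(parts)) {
      # partition property
      expect_setequal(names(parts[[k]]), ids)
      if (k > 1L) {
        lo <- parts[[k - 1L]]; hi <- parts[[k]]
        # each higher-tau cluster is contained in one lower-tau cluster
        for (cl in unique(hi)) {
          expect_equal(length(unique(lo[names(hi)[hi == cl]])), 1L)
        }
        expect_gte(length(unique(hi)), length(unique(lo)))
      }
    }
  }
})

test_that("aggregate_level computes mean/peak features and conserves mass", {
  ids <- c("a", "b", "c")
  feats <- matrix(c(1, 0, 0, 1, 5, 5), 3, 2, byrow = TRUE,
                  dimnames = list(ids, NULL))
  g <- build_affinity_graph(as_edge_table(toy_edges("a", "b", 0.9)), feats)
  sc <- linkage_scores(g, 0.9, c(a = 0.2, b = 0.8, c = 0.5))
  part <- c(a = "a", b = "a", c = "c")
  g1 <- aggregate_level(g, part, sc, k = 10)
  expect_equal(g1$level, 1L)
  expect_equal(g1$node_ids, c("a", "c"))
  expect_equal(unname(g1$features["a", ]), c(0.5, 0.5))   # mean of members
  expect_equal(unname(g1$peak_features["a", ]), c(0, 1))  # b is the peak
  expect_equal(sum(attr(g1, "n_members")), length(g$node_ids))

  # all singletons -> node count unchanged
  sing <- stats::setNames(ids, ids)
  expect_equal(length(aggregate_level(g, sing, sc, 2)$node_ids), 3L)

  # one all-covering cluster -> single node, no edges
  one <- stats::setNames(rep("a", 3), ids)
  g2 <- aggregate_level(g, one, sc, 5)
  expect_equal(length(g2$node_ids), 1L)
  expect_equal(nrow(g2$edges), 0L)
})

test_that("mutual-kNN wiring is symmetric, deterministic, weighted by cosine", {
  withr::local_seed(14)
  f <- matrix(rnorm(12 * 3), 12, dimnames = list(sprintf("x%02d", 1:12), NULL))
  ed <- hiersys:::mutual_knn_edges(f, 3)
  expect_true(all(ed$u < ed$v))
  expect_true(all(ed$weight <= 1 + 1e-12))
  fn <- f / sqrt(rowSums(f^2))
  expect_equal(ed$weight[1],
               sum(fn[ed$u[1], ] * fn[ed$v[1], ]), tolerance = 1e-12)
  expect_identical(ed, hiersys:::mutual_knn_edges(f, 3))
})

test_that("oracle-scored decoding recovers the planted hierarchy exactly", {
  # dense within-leaf connectivity so the planted partition is decodable
  d <- simulate_dataset(synthetic_spec(n_genes = 120, branching = c(10, 2),
                                       p_in = 1, p_out = 0.05, seed = 6))
  part_truth <- list(d$truth$level1, d$truth$level2)
  g_cur <- d$graph
  gene2node <- stats::setNames(d$graph$node_ids, d$graph$node_ids)
  for (lvl in 1:2) {
    # per-level oracle: current nodes labeled by their planted cluster
    rep_gene <- names(gene2node)[match(g_cur$node_ids, gene2node)]
    node_lab <- stats::setNames(part_truth[[lvl]][rep_gene], g_cur$node_ids)
    tg <- ground_truth_targets(g_cur, node_lab)
    sc <- linkage_scores(g_cur, tg$edge_target, tg$node_density)
    part <- decode_level(g_cur, sc, 0.5)
    gene_part <- stats::setNames(unname(part[gene2node]), names(gene2node))
    expect_equal(unname(pairwise_f(gene_part, part_truth[[lvl]])["f"]), 1,
                 label = sprintf("level %d Fp", lvl))
    g_cur <- aggregate_level(g_cur, part, sc, k = 10)
    gene2node <- stats::setNames(unname(part[gene2node]), names(gene2node))
  }
})

test_that("infer_hierarchy handles degenerate and bounded cases", {
  g <- chain4()
  m <- init_model(2, model_config(hidden_dim = 4, seed = 5))
  # force all probabilities below threshold: p_tau = 1 can never be beaten
  h0 <- infer_hierarchy(g, m, modifyList(m$config, list(p_tau = 1)))
  expect_equal(nrow(h0$systems), 0L)
  expect_equal(h0$genes, g$node_ids)

  # max_levels = 1 -> at most one system level
  h1 <- infer_hierarchy(g, m, modifyList(m$config, list(max_levels = 1L,
                                                        p_tau = 0)))
  expect_true(all(h1$systems$level <= 1L))
})

test_that("inference conserves genes and is deterministic end to end", {
  d <- simulate_dataset(synthetic_spec(n_genes = 90, branching = c(6, 2),
                                       seed = 11))
  sp <- split_nodes(d$graph$node_ids, seed = 11)
  cfg <- model_config(hidden_dim = 16, epochs = 40, learning_rate = 0.05,
                      seed = 11)
  m <- train_model(d$graph, d$labels, sp, cfg)
  h1 <- infer_hierarchy(d$graph, m)
  h2 <- infer_hierarchy(d$graph, m)
  expect_identical(h1, h2)
  expect_identical(h1$genes, d$graph$node_ids)
  # every gene reachable from exactly one root
  gs <- hier_gene_sets(h1)
  roots <- intersect(hier_roots(h1), h1$systems$id)
  root_genes <- unlist(gs[roots], use.names = FALSE)
  expect_equal(anyDuplicated(root_genes), 0L)
  expect_lte(max(h1$systems$level, 0L), m$config$max_levels)
})
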