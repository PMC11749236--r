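path3 <- function() {
  ids <- c("n1", "n2", "n3")
  feats <- matrix(c(1, 0, 0, 1, 1, 0), 3, 2, byrow = TRUE,
                  dimnames = list(ids, NULL))
  build_affinity_graph(as_edge_table(toy_edges(c("n1", "n2"),
                                               c("n2", "n3"), 1)), feats)
}

test_that("0-layer encode is exactly the input projection", {
  g <- path3()
  m <- init_model(2, model_config(mpgnn_layers = 0, hidden_dim = 3, seed = 2))
  H <- mpgnn_encode(g, m)
  X <- cbind(g$features, g$features)  # rows already unit norm
  expect_equal(unname(H),
               unname(X %*% m$params$W_in + rep(m$params$b_in, each = 3)),
               tolerance = 1e-12)
})

test_that("1-layer forward on a path with unit weights matches hand computation", {
  g <- path3()
  cfg <- model_config(mpgnn_layers = 1, hidden_dim = 2, seed = 3)
  m <- init_model(2, cfg)
  p <- m$params
  H <- mpgnn_encode(g, m)

  # hand-rolled oracle: explicit loops, mean aggregation
  relu0 <- function(x) pmax(x, 0)
  X <- cbind(g$features, g$features)
  H0 <- X %*% p$W_in + rep(p$b_in, each = 3)
  nbrs <- list(n1 = "n2", n2 = c("n1", "n3"), n3 = "n2")
  rownames(H0) <- g$node_ids
  Hexp <- H0
  for (i in g$node_ids) {
    msgs <- sapply(nbrs[[i]], function(j) {
      relu0(c(H0[i, ], H0[j, ], rep(1, 5)) %*% p$W_msg1 + p$b_msg1)
    })
    magg <- rowMeans(matrix(msgs, nrow = cfg$hidden_dim))
    Hexp[i, ] <- relu0(c(H0[i, ], magg) %*% p$W_upd1 + p$b_upd1)
  }
  expect_equal(unname(H), unname(Hexp), tolerance = 1e-12)
})

test_that("an isolated node's embedding ignores the rest of the graph", {
  ids <- sprintf("n%d", 1:4)
  withr::local_seed(8)
  feats <- matrix(rnorm(8), 4, dimnames = list(ids, NULL))
  g1 <- build_affinity_graph(as_edge_table(toy_edges(c("n1", "n2"),
                                                     c("n2", "n3"), 0.8)),
                             feats)
  feats2 <- feats
  feats2[1:3, ] <- feats2[1:3, ] + 5  # perturb everyone except isolated n4
  g2 <- build_affinity_graph(as_edge_table(toy_edges(c("n1", "n2"),
                                                     c("n2", "n3"), 0.8)),
                             feats2)
  m <- init_model(2, model_config(hidden_dim = 4, seed = 1))
  expect_equal(mpgnn_encode(g1, m)["n4", ], mpgnn_encode(g2, m)["n4", ],
               tolerance = 1e-12)
  expect_error(mpgnn_encode(toy_graph0(3, D = 5), m), "feature width")
})

test_that("analytic gradients match finite differences", {
  withr::local_seed(21)
  ids <- sprintf("n%d", 1:5)
  feats <- matrix(rnorm(15), 5, 3, dimnames = list(ids, NULL))
  ed <- toy_edges(c("n1", "n1", "n2", "n3"), c("n2", "n3", "n3", "n4"),
                  score = 0.5)
  ed$physical <- runif(4)
  g <- build_affinity_graph(as_edge_table(ed), feats)
  m <- init_model(3, model_config(mpgnn_layers = 2, hidden_dim = 3,
                                  seed = 4))
  lab <- stats::setNames(c("A", "A", "B", "B", "A"), ids)
  tg <- ground_truth_targets(g, lab)
  et <- tg$edge_target; em <- !is.na(et); et[!em] <- 0
  dt <- tg$node_density; dm <- !is.na(dt); dt[!dm] <- 0

  loss_at <- function(params) {
    m2 <- m; m2$params <- params
    fw <- hiersys:::mpgnn_forward(g, m2)
    hiersys:::mpgnn_loss_grads(g, m2, fw, et, em, dt, dm)$loss
  }
  fw <- hiersys:::mpgnn_forward(g, m)
  an <- hiersys:::mpgnn_loss_grads(g, m, fw, et, em, dt, dm)$grads

  eps <- 1e-6
  for (nm in c("W_in", "W_msg1", "W_upd2", "w_link", "w_dens", "b_msg2",
               "b_link")) {
    x <- m$params[[nm]]
    idx <- sample(length(x), min(4, length(x)))
    for (i in idx) {
      pp <- m$params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- m$params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
      expect_equal(as.vector(an[[nm]])[i], num, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("ground-truth targets follow the weighted density formula", {
  # 4-node toy, mixed labels, unit weights
  ed <- toy_edges(c("a", "a", "b", "c"), c("b", "c", "c", "d"), 1)
  feats <- matrix(0, 4, 2, dimnames = list(letters[1:4], NULL))
  g <- build_affinity_graph(as_edge_table(ed), feats)
  lab <- c(a = "X", b = "X", c = "Y", d = "Y")
  tg <- ground_truth_targets(g, lab)
  # edges sorted (a,b), (a,c), (b,c), (c,d): targets 1, 0, 0, 1
  expect_equal(tg$edge_target, c(1, 0, 0, 1))
  expect_equal(unname(tg$node_density[letters[1:4]]),
               c(0, 0, -1 / 3, 1))  # hand computation
  # node with all same-class neighbors -> +1; isolated -> 0
  g2 <- toy_graph0(3, toy_edges("n1", "n2", 0.4))
  tg2 <- ground_truth_targets(g2, c(n1 = "Z", n2 = "Z", n3 = "Z"))
  expect_equal(unname(tg2$node_density), c(1, 1, 0))
  # unlabeled nodes are masked
  tg3 <- ground_truth_targets(g2, c(n1 = "Z", n2 = "Z"))
  expect_true(is.na(tg3$node_density[["n3"]]))
})

test_that("training is seeded, monotone-ish, and epochs = 0 is the init", {
  d <- simulate_dataset(synthetic_spec(n_genes = 80, branching = c(6, 2),
                                       seed = 4))
  sp <- split_nodes(d$graph$node_ids, seed = 4)
  cfg0 <- model_config(hidden_dim = 8, epochs = 0, seed = 9)
  m0 <- train_model(d$graph, d$labels, sp, cfg0)
  expect_identical(m0$params, init_model(32, cfg0)$params)

  cfg <- model_config(hidden_dim = 8, epochs = 30, learning_rate = 0.05,
                      seed = 9)
  m1 <- train_model(d$graph, d$labels, sp, cfg)
  m2 <- train_model(d$graph, d$labels, sp, cfg)
  expect_identical(m1$params, m2$params)  # seeded determinism
  expect_lte(m1$history$loss[30], m1$history$loss[1])

  f <- withr::local_tempfile(fileext = ".rds")
  write_model(m1, f)
  expect_identical(read_model(f)$params, m1$params)

  g0 <- toy_graph0(4, D = 32)  # edgeless graph
  lab0 <- hiersys:::new_label_partition(
    stats::setNames(c("A", "A", "B", "B"), g0$node_ids))
  expect_error(train_model(g0, lab0,
                           list(train = g0$node_ids[1:3],
                                val = g0$node_ids[4], test = character(0)),
                           cfg),
               "no edges")
})

test_that("easy well-separated data trains to high validation Fp", {
  # labels at the finest planted level: supervision = target granularity
  d <- simulate_dataset(synthetic_spec(n_genes = 120, branching = c(8L),
                                       label_level = 1, seed = 0))
  sp <- split_nodes(d$graph$node_ids, seed = 0)
  cfg <- model_config(hidden_dim = 32, epochs = 80, learning_rate = 0.05,
                      seed = 0)
  m <- train_model(d$graph, d$labels, sp, cfg)
  fp <- m$history$val_fp
  expect_gte(fp[length(fp)], 0.9)
})
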