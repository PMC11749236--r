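#' Model configuration for the hierarchical clustering GNN
#'
#' @param mpgnn_layers number of message-passing layers (default 2).
#' @param hidden_dim hidden state width (default 256).
#' @param k nearest-neighbor degree used to wire graph levels >= 1
#'   (default 10; mutual-kNN under cosine similarity).
#' @param p_tau edge-keep probability threshold in `[0, 1]` used by the
#'   decoder (default 0.5).
#' @param max_levels maximum number of system levels (default 10).
#' @param loss_weights length-2 `(linkage, density)` loss weights.
#' @param epochs full-batch training epochs (default 200).
#' @param learning_rate Adam step size (default 0.05).
#' @param eval_every record validation pairwise-F every this many epochs.
#' @param seed integer seed controlling initialization and the split-free
#'   parts of training.
#' @return a `model_config` list.
#' @export
model_config <- function(mpgnn_layers = 2L, hidden_dim = 256L, k = 10L,
                         p_tau = 0.5, max_levels = 10L,
                         loss_weights = c(1, 1), epochs = 200L,
                         learning_rate = 0.05, eval_every = 10L, seed = 1L) {
  assert_scalar_number(p_tau, "p_tau", 0, 1)
  assert_scalar_number(max_levels, "max_levels", 1)
  assert_scalar_number(mpgnn_layers, "mpgnn_layers", 0)
  assert_scalar_number(hidden_dim, "hidden_dim", 1)
  assert_scalar_number(k, "k", 1)
  assert_scalar_number(epochs, "epochs", 0)
  assert_scalar_number(learning_rate, "learning_rate", 1e-12)
  stopifnot(length(loss_weights) == 2L, all(loss_weights >= 0))
  structure(list(mpgnn_layers = as.integer(mpgnn_layers),
                 hidden_dim = as.integer(hidden_dim), k = as.integer(k),
                 p_tau = p_tau, max_levels = as.integer(max_levels),
                 loss_weights = as.numeric(loss_weights),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 eval_every = as.integer(eval_every),
                 seed = as.integer(seed)),
            class = "model_config")
}

N_EDGE_FEAT <- 5L

relu <- function(x) (x > 0) * x

row_normalize <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  m / pmax(nrm, 1e-12)
}

# Node input: the mean-feature block and the peak-feature block (equal to
# the mean block at level 0), each row-L2-normalized so the geometry is
# scale-free across levels, then concatenated.
input_blocks <- function(graph) {
  mean_blk <- row_normalize(graph$features)
  peak_blk <- if (is.null(graph$peak_features)) mean_blk else
    row_normalize(graph$peak_features)
  cbind(mean_blk, peak_blk)
}

# Per-edge feature rows: the 5 association channels at level 0; at levels
# >= 1 the scalar similarity weight replicated across the 5 slots so one
# trained message/linkage transform serves every level.
edge_feature_matrix <- function(graph) {
  if (nrow(graph$edges) == 0L) {
    return(matrix(0, 0L, N_EDGE_FEAT))
  }
  if (graph$level == 0L) {
    as.matrix(graph$edges[CHANNELS])
  } else {
    matrix(rep(graph$edges$weight, N_EDGE_FEAT), ncol = N_EDGE_FEAT)
  }
}

glorot <- function(nr, nc) {
  matrix(rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc)
}

#' Initialize model parameters
#'
#' @param feature_dim width D of one node feature block (the encoder input
#'   is `2 * D`: mean block plus peak block).
#' @param config a [model_config()].
#' @return a `hilander_model` with seeded parameters and empty history.
#' @export
init_model <- function(feature_dim, config = model_config()) {
  h <- config$hidden_dim
  with_seed(config$seed, {
    params <- list(W_in = glorot(2L * feature_dim, h), b_in = numeric(h))
    for (l in seq_len(config$mpgnn_layers)) {
      params[[paste0("W_msg", l)]] <- glorot(2L * h + N_EDGE_FEAT, h)
      params[[paste0("b_msg", l)]] <- numeric(h)
      params[[paste0("W_upd", l)]] <- glorot(2L * h, h)
      params[[paste0("b_upd", l)]] <- numeric(h)
    }
    params$w_link <- rnorm(4L * h + N_EDGE_FEAT, sd = 0.01)
    params$b_link <- 0
    params$w_dens <- rnorm(h, sd = 0.01)
    params$b_dens <- 0
    structure(list(params = params, config = config,
                   feature_dim = as.integer(feature_dim),
                   history = data.frame(epoch = integer(), loss = numeric(),
                                        val_fp = numeric())),
              class = "hilander_model")
  })
}

#' @export
print.hilander_model <- function(x, ...) {
  cat(sprintf(
    "<hilander_model> D=%d, hidden=%d, layers=%d, %d epoch(s) trained\n",
    x$feature_dim, x$config$hidden_dim, x$config$mpgnn_layers,
    nrow(x$history)))
  invisible(x)
}

# Full forward pass; returns all intermediates needed for backprop.
mpgnn_forward <- function(graph, model) {
  p <- model$params
  cfg <- model$config
  n <- length(graph$node_ids)
  if (ncol(graph$features) != model$feature_dim) {
    stop_hiersys("graph feature width ", ncol(graph$features),
                 " does not match model feature_dim ", model$feature_dim)
  }
  X <- input_blocks(graph)
  E1 <- edge_feature_matrix(graph)
  ui <- match(graph$edges$u, graph$node_ids)
  vi <- match(graph$edges$v, graph$node_ids)
  # directed expansion: receiver i, sender j
  iu <- c(ui, vi); jv <- c(vi, ui)
  E2 <- rbind(E1, E1)
  deg <- tabulate(iu, nbins = n)
  H <- X %*% p$W_in
  H <- H + rep(p$b_in, each = n)
  layers <- vector("list", cfg$mpgnn_layers)
  for (l in seq_len(cfg$mpgnn_layers)) {
    Hprev <- H
    if (length(iu)) {
      Araw <- cbind(Hprev[iu, , drop = FALSE], Hprev[jv, , drop = FALSE], E2)
      Mraw <- Araw %*% p[[paste0("W_msg", l)]]
      Mraw <- Mraw + rep(p[[paste0("b_msg", l)]], each = nrow(Mraw))
      Mact <- relu(Mraw)
      Magg <- matrix(0, n, cfg$hidden_dim)
      rs <- rowsum(Mact, iu)
      idx <- as.integer(rownames(rs))
      Magg[idx, ] <- rs / deg[idx]
    } else {
      Araw <- NULL; Mraw <- NULL; Mact <- NULL
      Magg <- matrix(0, n, cfg$hidden_dim)
    }
    U <- cbind(Hprev, Magg)
    pre <- U %*% p[[paste0("W_upd", l)]]
    pre <- pre + rep(p[[paste0("b_upd", l)]], each = n)
    H <- relu(pre)
    layers[[l]] <- list(Hprev = Hprev, Araw = Araw, Mraw = Mraw, Mact = Mact,
                        Magg = Magg, U = U, pre = pre)
  }
  nrm <- pmax(sqrt(rowSums(H^2)), 1e-12)
  S <- H / nrm
  # heads
  h <- cfg$hidden_dim
  dens_pre <- drop(S %*% p$w_dens) + p$b_dens
  dens <- tanh(dens_pre)
  if (length(ui)) {
    Su <- S[ui, , drop = FALSE]; Sv <- S[vi, , drop = FALSE]
    Z <- cbind(Su, Sv, abs(Su - Sv), Su * Sv, E1)
    logit <- drop(Z %*% p$w_link) + p$b_link
    prob <- 1 / (1 + exp(-logit))
  } else {
    Su <- Sv <- Z <- NULL
    logit <- prob <- numeric(0)
  }
  list(X = X, E1 = E1, E2 = E2, ui = ui, vi = vi, iu = iu, jv = jv,
       deg = deg, layers = layers, H = H, nrm = nrm, S = S,
       dens_pre = dens_pre, dens = dens, Su = Su, Sv = Sv, Z = Z,
       logit = logit, prob = prob, n = n)
}

#' Encode graph nodes with the message-passing layers
#'
#' Runs the input projection and the configured number of message-passing
#' layers. With 0 layers the result is the input projection of the
#' (normalized) feature blocks. Each layer updates a node from its own
#' state and the mean of messages computed from (receiver state, sender
#' state, edge features); nodes without neighbors are updated from their
#' own state only.
#'
#' @param graph a `level_graph` whose feature width matches the model.
#' @param model a `hilander_model`.
#' @return n x hidden_dim matrix of node embeddings (unnormalized), node
#'   ids as row names.
#' @export
mpgnn_encode <- function(graph, model) {
  fw <- mpgnn_forward(graph, model)
  H <- if (model$config$mpgnn_layers == 0L) {
    fw$X %*% model$params$W_in + rep(model$params$b_in, each = fw$n)
  } else {
    fw$H
  }
  rownames(H) <- graph$node_ids
  H
}

#' Score a graph with the trained linkage and density heads
#'
#' @inheritParams mpgnn_encode
#' @return a `linkage_scores` object: `edge_prob` (one probability per row
#'   of `graph$edges`) and `node_density` (named per node).
#' @export
predict_linkage <- function(graph, model) {
  fw <- mpgnn_forward(graph, model)
  new_linkage_scores(graph, fw$prob, stats::setNames(fw$dens, graph$node_ids))
}

#' Construct linkage scores explicitly
#'
#' Mostly useful for oracle-scored decoding: e.g. feeding
#' [ground_truth_targets()] output through [decode_level()] to check what
#' a perfect model would recover.
#'
#' @param graph the `level_graph` the scores refer to.
#' @param edge_prob numeric vector in `[0, 1]`, one entry per row of
#'   `graph$edges` (NA allowed; treated as below any threshold).
#' @param node_density numeric vector named by node id.
#' @return a `linkage_scores` object.
#' @export
linkage_scores <- function(graph, edge_prob, node_density) {
  new_linkage_scores(graph, edge_prob, node_density)
}

new_linkage_scores <- function(graph, edge_prob, node_density) {
  if (length(edge_prob) != nrow(graph$edges)) {
    stop_hiersys("edge_prob must score every graph edge")
  }
  if (any(edge_prob < 0 | edge_prob > 1, na.rm = TRUE)) {
    stop_hiersys("edge probabilities must lie in [0, 1]")
  }
  structure(list(edge_prob = as.numeric(edge_prob),
                 node_density = node_density[graph$node_ids]),
            class = "linkage_scores")
}

# loss + gradients for one graph given targets; returns list(loss, grads)
mpgnn_loss_grads <- function(graph, model, fw, edge_target, edge_mask,
                             dens_target, dens_mask) {
  p <- model$params
  cfg <- model$config
  h <- cfg$hidden_dim
  w1 <- cfg$loss_weights[1L]; w2 <- cfg$loss_weights[2L]
  n <- fw$n
  grads <- lapply(p, function(x) if (is.matrix(x)) 0 * x else numeric(length(x)))
  grad_S <- matrix(0, n, h)

  ne <- sum(edge_mask)
  loss_link <- 0
  if (ne > 0L) {
    pr <- fw$prob[edge_mask]
    tg <- edge_target[edge_mask]
    eps <- 1e-12
    loss_link <- -mean(tg * log(pr + eps) + (1 - tg) * log(1 - pr + eps))
    glogit <- numeric(length(fw$prob))
    glogit[edge_mask] <- w1 * (pr - tg) / ne
    Zg <- fw$Z * glogit
    grads$w_link <- colSums(Zg)
    grads$b_link <- sum(glogit)
    wa <- p$w_link[seq_len(h)]
    wb <- p$w_link[h + seq_len(h)]
    wc <- p$w_link[2L * h + seq_len(h)]
    wd <- p$w_link[3L * h + seq_len(h)]
    SGN <- sign(fw$Su - fw$Sv)
    Gsu <- outer(glogit, wa) + outer(glogit, wc) * SGN +
      outer(glogit, wd) * fw$Sv
    Gsv <- outer(glogit, wb) - outer(glogit, wc) * SGN +
      outer(glogit, wd) * fw$Su
    ru <- rowsum(Gsu, fw$ui); grad_S[as.integer(rownames(ru)), ] <-
      grad_S[as.integer(rownames(ru)), ] + ru
    rv <- rowsum(Gsv, fw$vi); grad_S[as.integer(rownames(rv)), ] <-
      grad_S[as.integer(rownames(rv)), ] + rv
  }

  nd <- sum(dens_mask)
  loss_dens <- 0
  if (nd > 0L) {
    diff <- fw$dens - dens_target
    diff[!dens_mask] <- 0
    loss_dens <- sum(diff^2) / nd
    gpre <- (2 * w2 * diff / nd) * (1 - fw$dens^2)
    grads$w_dens <- drop(crossprod(fw$S, gpre))
    grads$b_dens <- sum(gpre)
    grad_S <- grad_S + outer(gpre, p$w_dens)
  }

  # back through L2 normalization: s = h / max(||h||, eps)
  dotSG <- rowSums(grad_S * fw$S)
  grad_H <- (grad_S - fw$S * dotSG) / fw$nrm

  for (l in rev(seq_len(cfg$mpgnn_layers))) {
    ly <- fw$layers[[l]]
    Gpre <- grad_H * (ly$pre > 0)
    grads[[paste0("W_upd", l)]] <- crossprod(ly$U, Gpre)
    grads[[paste0("b_upd", l)]] <- colSums(Gpre)
    GU <- Gpre %*% t(p[[paste0("W_upd", l)]])
    grad_Hprev <- GU[, seq_len(h), drop = FALSE]
    grad_Magg <- GU[, h + seq_len(h), drop = FALSE]
    if (length(fw$iu)) {
      Gmact <- grad_Magg[fw$iu, , drop = FALSE] / fw$deg[fw$iu]
      Gmraw <- Gmact * (ly$Mraw > 0)
      grads[[paste0("W_msg", l)]] <- crossprod(ly$Araw, Gmraw)
      grads[[paste0("b_msg", l)]] <- colSums(Gmraw)
      GA <- Gmraw %*% t(p[[paste0("W_msg", l)]])
      g1 <- rowsum(GA[, seq_len(h), drop = FALSE], fw$iu)
      grad_Hprev[as.integer(rownames(g1)), ] <-
        grad_Hprev[as.integer(rownames(g1)), ] + g1
      g2 <- rowsum(GA[, h + seq_len(h), drop = FALSE], fw$jv)
      grad_Hprev[as.integer(rownames(g2)), ] <-
        grad_Hprev[as.integer(rownames(g2)), ] + g2
    }
    grad_H <- grad_Hprev
  }
  grads$W_in <- crossprod(fw$X, grad_H)
  grads$b_in <- colSums(grad_H)
  list(loss = w1 * loss_link + w2 * loss_dens, grads = grads)
}

adam_init <- function(params) {
  list(m = lapply(params, function(x) 0 * x),
       v = lapply(params, function(x) 0 * x), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Ground-truth linkage and density targets from a label partition
#'
#' An edge's target is 1 iff its endpoints share a class. A node's density
#' target is the edge-weighted balance of same-class vs other-class
#' neighbors, `sum_j s_ij a_ij / sum_j s_ij` with `a_ij = +1` when i and j
#' share a class and `-1` otherwise, where `s_ij` is the mean of the
#' edge's five channel scores at level 0 or its similarity weight above;
#' a node with no (labeled) neighbor has density 0 by convention. Edges
#' with an unlabeled endpoint and unlabeled nodes are masked `NA`.
#'
#' @param graph a `level_graph`.
#' @param labels a `label_partition` or named vector node id -> class.
#' @return list with `edge_target` (0/1/NA per edge row), `node_density`
#'   (named, NA for unlabeled nodes), and `edge_weight` (the `s_ij` used).
#' @export
ground_truth_targets <- function(graph, labels) {
  lab <- if (inherits(labels, "label_partition")) labels$labels else labels
  lu <- lab[graph$edges$u]; lv <- lab[graph$edges$v]
  edge_target <- unname(ifelse(is.na(lu) | is.na(lv), NA_real_,
                               as.numeric(lu == lv)))
  ew <- if (graph$level == 0L) {
    if (nrow(graph$edges)) rowMeans(as.matrix(graph$edges[CHANNELS])) else numeric(0)
  } else {
    graph$edges$weight
  }
  dens <- stats::setNames(rep(0, length(graph$node_ids)), graph$node_ids)
  num <- den <- dens
  ok <- !is.na(edge_target)
  a <- 2 * edge_target[ok] - 1
  w <- ew[ok]
  for (side in 1:2) {
    ids <- if (side == 1L) graph$edges$u[ok] else graph$edges$v[ok]
    add <- tapply(a * w, ids, sum)
    num[names(add)] <- num[names(add)] + add
    addw <- tapply(w, ids, sum)
    den[names(addw)] <- den[names(addw)] + addw
  }
  dens <- ifelse(den > 0, num / pmax(den, 1e-300), 0)
  dens[!graph$node_ids %in% names(lab)] <- NA_real_
  names(dens) <- graph$node_ids
  list(edge_target = edge_target, node_density = dens, edge_weight = ew)
}

#' Train the linkage/density model on a labeled level-0 graph
#'
#' Full-batch Adam on
#' `w1 * BCE(edge probabilities, same-class targets) +
#'  w2 * MSE(node densities, weighted same-class balance)`,
#' restricted to the training-node induced subgraph (no label leakage
#' through loss edges). Validation pairwise-F is recorded every
#' `eval_every` epochs by decoding the full graph with the current
#' parameters and comparing the validation nodes' clusters to their
#' labels. Deterministic given `config$seed`.
#'
#' @param graph the level-0 `level_graph`.
#' @param labels a `label_partition`.
#' @param split list with `train`, `val`, `test` id vectors
#'   (see [split_nodes()]).
#' @param config a [model_config()].
#' @return a trained `hilander_model` (with `history`).
#' @export
train_model <- function(graph, labels, split, config = model_config()) {
  lab <- labels$labels
  gtrain <- induced_subgraph(graph, intersect(split$train, graph$node_ids))
  if (nrow(gtrain$edges) == 0L) {
    stop_hiersys("training-node induced subgraph has no edges")
  }
  model <- init_model(ncol(graph$features), config)
  tg <- ground_truth_targets(gtrain, lab)
  edge_mask <- !is.na(tg$edge_target)
  dens_mask <- !is.na(tg$node_density)
  et <- tg$edge_target; et[!edge_mask] <- 0
  dt <- tg$node_density; dt[!dens_mask] <- 0
  if (!any(edge_mask)) stop_hiersys("no labeled training edges")
  st <- adam_init(model$params)
  hist <- vector("list", config$epochs)
  val_ids <- intersect(split$val, names(lab))
  for (ep in seq_len(config$epochs)) {
    fw <- mpgnn_forward(gtrain, model)
    lg <- mpgnn_loss_grads(gtrain, model, fw, et, edge_mask, dt, dens_mask)
    upd <- adam_step(model$params, lg$grads, st, config$learning_rate)
    model$params <- upd$params; st <- upd$state
    val_fp <- NA_real_
    if (length(val_ids) >= 2L &&
        (ep %% config$eval_every == 0L || ep == config$epochs)) {
      part <- decode_level(graph, predict_linkage(graph, model), config$p_tau)
      val_fp <- unname(pairwise_f(part[val_ids], lab[val_ids])["f"])
    }
    hist[[ep]] <- data.frame(epoch = ep, loss = lg$loss, val_fp = val_fp)
  }
  model$history <- if (config$epochs > 0L) do.call(rbind, hist) else
    data.frame(epoch = integer(), loss = numeric(), val_fp = numeric())
  model
}

#' Induced subgraph on a node subset
#' @param graph a `level_graph`.
#' @param ids node ids to keep.
#' @return a `level_graph` on `ids` with internal edges only.
#' @export
induced_subgraph <- function(graph, ids) {
  ids <- sort(intersect(ids, graph$node_ids), method = "radix")
  keep <- graph$edges$u %in% ids & graph$edges$v %in% ids
  new_level_graph(graph$level, ids, graph$features[ids, , drop = FALSE],
                  if (is.null(graph$peak_features)) NULL else
                    graph$peak_features[ids, , drop = FALSE],
                  graph$edges[keep, , drop = FALSE])
}

#' Save / load a trained model
#'
#' RDS-based; a reloaded model is bit-identical.
#' @param model a `hilander_model`.
#' @param path file path.
#' @export
write_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "hilander_model")) stop_hiersys("not a saved model: ", path)
  m
}
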