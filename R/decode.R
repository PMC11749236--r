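#' Decode one graph level into clusters
#'
#' Peak-seeking edge selection: every node keeps at most one incident
#' edge — toward the neighbor with the highest linkage probability among
#' those with probability at least `p_tau` and density at least the
#' node's own (ties broken by the smaller neighbor id). Clusters are the
#' connected components of the kept edges. Raising `p_tau` can only
#' shrink the kept-edge set, so it never merges two previously separate
#' clusters.
#'
#' @param graph a `level_graph`.
#' @param scores a `linkage_scores` covering all edges of `graph`.
#' @param p_tau probability threshold in `[0, 1]`.
#' @return named character vector: node id -> cluster id (smallest member
#'   id of the component). The kept edges are attached as attribute
#'   `"kept_edges"`.
#' @export
decode_level <- function(graph, scores, p_tau = 0.5) {
  stopifnot(inherits(scores, "linkage_scores"))
  assert_scalar_number(p_tau, "p_tau", 0, 1)
  ed <- graph$edges
  prob <- scores$edge_prob
  if (length(prob) != nrow(ed)) stop_hiersys("scores do not cover all edges")
  dens <- scores$node_density
  # directed view: node i considers neighbor j
  cand <- data.frame(
    i = c(ed$u, ed$v), j = c(ed$v, ed$u),
    prob = c(prob, prob), eid = c(seq_len(nrow(ed)), seq_len(nrow(ed))),
    stringsAsFactors = FALSE)
  cand <- cand[cand$prob >= p_tau & !is.na(cand$prob), , drop = FALSE]
  cand <- cand[dens[cand$j] >= dens[cand$i], , drop = FALSE]
  kept <- integer(0)
  if (nrow(cand)) {
    cand <- cand[order(cand$i, -cand$prob, cand$j, method = "radix"), ,
                 drop = FALSE]
    kept <- unique(cand$eid[!duplicated(cand$i)])
  }
  part <- comp_of_edges(graph$node_ids, ed[kept, , drop = FALSE])
  attr(part, "kept_edges") <- ed[sort(kept), c("u", "v"), drop = FALSE]
  part
}

#' Aggregate clusters into the next graph level
#'
#' One node per cluster, carrying two feature blocks: the mean feature
#' (average of the members' mean features) and the peak feature (the mean
#' feature of the member with the highest predicted density; ties to the
#' smaller id). New edges connect mutual k-nearest neighbors under cosine
#' similarity on the mean features, with the similarity as the scalar
#' edge weight. Deterministic.
#'
#' @param graph the current `level_graph`.
#' @param clusters named vector node id -> cluster id (a partition of the
#'   graph's nodes, e.g. from [decode_level()]).
#' @param scores the `linkage_scores` used to decode (for density peaks).
#' @param k mutual-kNN degree (capped at node count minus 1).
#' @return a `level_graph` at `graph$level + 1` whose node ids are the
#'   cluster ids; cluster membership is attached as attribute `"members"`
#'   and per-node member counts as `"n_members"`.
#' @export
aggregate_level <- function(graph, clusters, scores, k = 10L) {
  clusters <- clusters[graph$node_ids]
  if (anyNA(clusters)) stop_hiersys("clusters must cover every graph node")
  dens <- scores$node_density
  members <- split(graph$node_ids, clusters)
  members <- members[sort(names(members), method = "radix")]
  ids <- names(members)
  m <- length(ids)
  D <- ncol(graph$features)
  mean_f <- matrix(0, m, D, dimnames = list(ids, NULL))
  peak_f <- matrix(0, m, D, dimnames = list(ids, NULL))
  for (c in seq_len(m)) {
    mem <- members[[c]]
    fm <- graph$features[mem, , drop = FALSE]
    mean_f[c, ] <- colMeans(fm)
    peak <- mem[order(-dens[mem], mem)][1L]
    peak_f[c, ] <- graph$features[peak, ]
  }
  edges <- mutual_knn_edges(mean_f, k)
  g <- new_level_graph(graph$level + 1L, ids, mean_f, peak_f, edges)
  attr(g, "members") <- members
  attr(g, "n_members") <- stats::setNames(lengths(members), ids)
  g
}

# mutual k-nearest-neighbor edge list under cosine similarity
mutual_knn_edges <- function(features, k) {
  m <- nrow(features)
  if (m < 2L || k < 1L) {
    return(data.frame(u = character(), v = character(), weight = numeric()))
  }
  k <- min(k, m - 1L)
  Xn <- row_normalize(features)
  sim <- Xn %*% t(Xn)
  diag(sim) <- -Inf
  ids <- rownames(features)
  nb <- vector("list", m)
  for (i in seq_len(m)) {
    ord <- order(-sim[i, ], ids)
    nb[[i]] <- ord[seq_len(k)]
  }
  u <- character(0); v <- character(0); w <- numeric(0)
  for (i in seq_len(m)) {
    for (j in nb[[i]]) {
      if (j > i && i %in% nb[[j]]) {
        u <- c(u, ids[i]); v <- c(v, ids[j]); w <- c(w, sim[i, j])
      }
    }
  }
  ed <- data.frame(u = pmin(u, v), v = pmax(u, v), weight = w,
                   stringsAsFactors = FALSE)
  ed[order(ed$u, ed$v, method = "radix"), , drop = FALSE]
}

#' Infer a full hierarchy by iterating score, decode, aggregate
#'
#' Starting from the level-0 affinity graph, each iteration scores the
#' current graph with the trained model, decodes clusters, promotes every
#' cluster with at least two members to a new system, and aggregates the
#' clusters into the next graph level. Singleton clusters pass through
#' unchanged (no system is created for them). Iteration stops when no
#' non-singleton cluster is found or `max_levels` is reached. The result
#' is deterministic given (graph, model, config).
#'
#' @param graph the level-0 `level_graph` (its node ids are the genes).
#' @param model a trained `hilander_model`.
#' @param config optional [model_config()]; defaults to the model's own.
#' @return a `hierarchy` over the graph's node ids.
#' @export
infer_hierarchy <- function(graph, model, config = NULL) {
  config <- config %||% model$config
  genes <- graph$node_ids
  node2h <- stats::setNames(genes, genes)  # graph node id -> hierarchy id
  systems <- list()
  children <- list()
  g <- graph
  sys_n <- 0L
  for (lvl in seq_len(config$max_levels)) {
    if (length(g$node_ids) < 2L || nrow(g$edges) == 0L) break
    scores <- predict_linkage(g, model)
    part <- decode_level(g, scores, config$p_tau)
    sizes <- table(part)
    if (all(sizes < 2L)) break
    new_map <- character(0)
    for (cid in sort(unique(part), method = "radix")) {
      mem <- names(part)[part == cid]
      if (length(mem) >= 2L) {
        sys_n <- sys_n + 1L
        sid <- sprintf("S%d_%04d", lvl, sys_n)
        systems[[sid]] <- data.frame(id = sid, level = lvl,
                                     stringsAsFactors = FALSE)
        children[[sid]] <- unname(node2h[mem])
        new_map[cid] <- sid
      } else {
        new_map[cid] <- node2h[[mem]]
      }
    }
    g <- aggregate_level(g, part, scores, config$k)
    node2h <- new_map[g$node_ids]
    names(node2h) <- g$node_ids
  }
  sys_df <- if (length(systems)) do.call(rbind, systems) else
    data.frame(id = character(), level = integer())
  new_hierarchy(genes, sys_df, children)
}
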