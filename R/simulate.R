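#' Specification of a planted synthetic world
#'
#' Describes a planted multi-level community structure with
#' cluster-informative node features, channelized edge weights, flat
#' cluster-derived labels, and burden signals elevated on planted
#' systems — a deterministic stand-in for the real sequence/PPI/GO/omics
#' inputs, so every pipeline stage is testable offline.
#'
#' Feature generation is hierarchically Gaussian: a child cluster's mean
#' is its parent's mean plus `Normal(0, between_sd^2)` noise per
#' dimension, and a gene's feature is its leaf-cluster mean plus
#' `Normal(0, within_sd^2)` noise, so deeper clusters are tighter. The
#' five edge channels share one law: an edge is present with probability
#' `p_in` within a leaf cluster and `p_out` between, with channel scores
#' `Normal(mu_in, channel_sd^2)` / `Normal(mu_out, channel_sd^2)` clipped
#' at 0.
#'
#' @param n_genes number of gene leaves (default 300).
#' @param branching per-level cluster counts from leaves up (default
#'   `c(20, 5)`: 20 leaf clusters inside 5 super-clusters); counts must be
#'   non-increasing upward.
#' @param feature_dim node feature width (default 32 — a scaled-down
#'   stand-in for 1280-wide language-model embeddings).
#' @param within_sd,between_sd hierarchical Gaussian noise scales
#'   (defaults 0.2 and 1.0; `within_sd < between_sd`).
#' @param p_in,p_out edge probabilities within/between leaf clusters
#'   (defaults 0.9, 0.02).
#' @param mu_in,mu_out mean channel score within/between leaf clusters
#'   (defaults 0.8, 0.1; `mu_in > mu_out`); `channel_sd` the common score
#'   noise (0.1).
#' @param label_level planted level whose cluster ids serve as the flat
#'   supervision classes. Defaults to the top level: supervision coarser
#'   than the finest planted structure, the way GO classes are coarser
#'   than tight complexes, so the inferred hierarchy has levels below the
#'   label granularity.
#' @param planted_systems number of leaf-level systems carrying elevated
#'   burden (default 3).
#' @param effect_size,base_rate burden signal parameters (defaults 3, 1).
#' @param seed master seed.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_genes = 300L, branching = c(20L, 5L),
                           feature_dim = 32L, within_sd = 0.2,
                           between_sd = 1.0, p_in = 0.9, p_out = 0.02,
                           mu_in = 0.8, mu_out = 0.1, channel_sd = 0.1,
                           label_level = NULL, planted_systems = 3L,
                           effect_size = 3, base_rate = 1, seed = 1L) {
  label_level <- label_level %||% length(branching)
  spec <- list(n_genes = as.integer(n_genes), branching = as.integer(branching),
               feature_dim = as.integer(feature_dim), within_sd = within_sd,
               between_sd = between_sd, p_in = p_in, p_out = p_out,
               mu_in = mu_in, mu_out = mu_out, channel_sd = channel_sd,
               label_level = as.integer(label_level),
               planted_systems = as.integer(planted_systems),
               effect_size = effect_size, base_rate = base_rate,
               seed = as.integer(seed))
  if (any(spec$branching < 1L) || spec$branching[1L] > spec$n_genes) {
    stop_hiersys("infeasible branching: more clusters than genes")
  }
  if (length(spec$branching) > 1L && any(diff(spec$branching) > 0L)) {
    stop_hiersys("branching sizes must be non-increasing upward")
  }
  if (spec$label_level > length(spec$branching) || spec$label_level < 1L) {
    stop_hiersys("label_level must index a planted level")
  }
  for (p in c("p_in", "p_out")) assert_scalar_number(spec[[p]], p, 0, 1)
  if (spec$mu_in <= spec$mu_out) stop_hiersys("mu_in must exceed mu_out")
  if (spec$within_sd >= spec$between_sd) {
    stop_hiersys("within_sd must be below between_sd")
  }
  if (spec$planted_systems > sum(spec$branching)) {
    stop_hiersys("more planted systems than systems")
  }
  structure(spec, class = "synthetic_spec")
}

#' Generate a planted synthetic dataset
#'
#' Regeneration from the same spec (which includes the seed) is
#' bit-identical. Planted system ids are drawn among the leaf-level
#' systems; burden tracks are generated by [simulate_signals()] with seed
#' `spec$seed + 1`.
#'
#' @param spec a [synthetic_spec()].
#' @return a `synthetic_dataset`: list with `graph` (the level-0
#'   `level_graph`), `labels` (`label_partition`), `hierarchy` (planted
#'   truth), `tracks` (list of `signal_track`s `counts` and `zscores`),
#'   `planted` (burdened system ids), `truth` (named list: per planted
#'   level, the gene -> cluster-id partition), and the `spec`.
#' @export
simulate_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_genes
  D <- spec$feature_dim
  nl <- length(spec$branching)
  genes <- sprintf("g%04d", seq_len(n))
  sys_id <- function(lvl, idx) sprintf("C%d_%02d", lvl, idx)

  out <- with_seed(spec$seed, {
    # balanced assignments: genes -> leaf clusters, clusters -> parents
    assign <- vector("list", nl)
    assign[[1L]] <- sort(rep_len(seq_len(spec$branching[1L]), n))
    parent_of <- vector("list", nl)
    for (lvl in seq2(2L, nl)) {
      parent_of[[lvl]] <- sort(rep_len(seq_len(spec$branching[lvl]),
                                       spec$branching[lvl - 1L]))
      assign[[lvl]] <- parent_of[[lvl]][assign[[lvl - 1L]]]
    }
    # hierarchical Gaussian means, sampled top-down from a zero root
    means <- vector("list", nl)
    means[[nl]] <- matrix(rnorm(spec$branching[nl] * D, sd = spec$between_sd),
                          ncol = D)
    for (lvl in rev(seq2(1L, nl - 1L))) {
      means[[lvl]] <- means[[lvl + 1L]][parent_of[[lvl + 1L]], , drop = FALSE] +
        matrix(rnorm(spec$branching[lvl] * D, sd = spec$between_sd), ncol = D)
    }
    feat <- means[[1L]][assign[[1L]], , drop = FALSE] +
      matrix(rnorm(n * D, sd = spec$within_sd), ncol = D)
    rownames(feat) <- genes

    # channelized edges over all gene pairs
    pr <- utils::combn(n, 2L)
    same <- assign[[1L]][pr[1L, ]] == assign[[1L]][pr[2L, ]]
    keep <- runif(ncol(pr)) < ifelse(same, spec$p_in, spec$p_out)
    iu <- pr[1L, keep]; iv <- pr[2L, keep]; within <- same[keep]
    ne <- length(iu)
    ch <- matrix(pmax(0, rnorm(ne * 5L,
                               mean = rep(ifelse(within, spec$mu_in,
                                                 spec$mu_out), 5L),
                               sd = spec$channel_sd)),
                 ncol = 5L, dimnames = list(NULL, CHANNELS))
    edges <- data.frame(u = genes[iu], v = genes[iv], ch,
                        stringsAsFactors = FALSE)
    planted <- sys_id(1L, sort(sample.int(spec$branching[1L],
                                          spec$planted_systems)))
    list(assign = assign, parent_of = parent_of, feat = feat, edges = edges,
         planted = planted)
  })

  graph <- build_affinity_graph(as_edge_table(out$edges), out$feat)
  labels <- new_label_partition(
    stats::setNames(sys_id(spec$label_level,
                           out$assign[[spec$label_level]]), genes),
    branch = "GO")

  systems <- list(); children <- list()
  for (lvl in seq_len(nl)) {
    for (cidx in seq_len(spec$branching[lvl])) {
      sid <- sys_id(lvl, cidx)
      systems[[sid]] <- data.frame(id = sid, level = lvl,
                                   stringsAsFactors = FALSE)
      children[[sid]] <- if (lvl == 1L) {
        genes[out$assign[[1L]] == cidx]
      } else {
        sys_id(lvl - 1L, which(out$parent_of[[lvl]] == cidx))
      }
    }
  }
  hierarchy <- new_hierarchy(genes, do.call(rbind, systems), children)
  tracks <- simulate_signals(hierarchy, out$planted, spec$effect_size,
                             spec$base_rate, seed = spec$seed + 1L)
  truth <- lapply(seq_len(nl), function(lvl) {
    stats::setNames(sys_id(lvl, out$assign[[lvl]]), genes)
  })
  names(truth) <- paste0("level", seq_len(nl))
  structure(list(graph = graph, labels = labels, hierarchy = hierarchy,
                 tracks = tracks, planted = out$planted, truth = truth,
                 spec = spec),
            class = "synthetic_dataset")
}

#' Simulate burden signal tracks on a hierarchy
#'
#' Genes inside any planted system get an elevated signal: the count-like
#' track is `Poisson(base_rate + effect_size * planted)` (mutation-burden
#' analogue) and the z-like track is `Normal(effect_size * planted, 1)`
#' (meta-z analogue, transform `"abs"`). Deterministic per seed.
#'
#' @param hierarchy a `hierarchy`.
#' @param planted character vector of system ids carrying the burden.
#' @param effect_size added rate / mean shift for planted genes.
#' @param base_rate background Poisson rate.
#' @param seed integer seed.
#' @return list of `signal_track`s: `counts` and `zscores`.
#' @export
simulate_signals <- function(hierarchy, planted, effect_size = 3,
                             base_rate = 1, seed = 1L) {
  unknown <- setdiff(planted, hierarchy$systems$id)
  if (length(unknown)) {
    stop_hiersys("planted systems not in hierarchy: ",
                 paste(unknown, collapse = ", "))
  }
  genes <- hierarchy$genes
  gs <- hier_gene_sets(hierarchy)
  hit <- genes %in% unique(unlist(gs[planted], use.names = FALSE))
  with_seed(seed, {
    counts <- rpois(length(genes), base_rate + effect_size * hit)
    zs <- rnorm(length(genes), mean = effect_size * hit, sd = 1)
    list(counts = signal_track("counts",
                               stats::setNames(as.numeric(counts), genes)),
         zscores = signal_track("zscores", stats::setNames(zs, genes),
                                transform = "abs"))
  })
}

#' Write a synthetic dataset to a directory
#'
#' Emits `edges.tsv`, `features.tsv`, `labels.tsv`, `truth.ont`,
#' `signals_counts.tsv`, `signals_zscores.tsv`, and `planted.txt`.
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ed <- dataset$graph$edges
  class(ed) <- c("edge_table", "data.frame")
  write_edge_table(ed, file.path(dir, "edges.tsv"))
  write_feature_matrix(dataset$graph$features, file.path(dir, "features.tsv"))
  utils::write.table(
    data.frame(gene = names(dataset$labels$labels),
               term = unname(dataset$labels$labels)),
    file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_ontology(dataset$hierarchy, file.path(dir, "truth.ont"))
  for (nm in names(dataset$tracks)) {
    tr <- dataset$tracks[[nm]]
    utils::write.table(
      data.frame(gene_id = names(tr$values), value = fmt_num(tr$values)),
      file.path(dir, paste0("signals_", nm, ".tsv")), sep = "\t",
      quote = FALSE, row.names = FALSE)
  }
  writeLines(dataset$planted, file.path(dir, "planted.txt"))
  invisible(dir)
}
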