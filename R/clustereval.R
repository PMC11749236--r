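#' Clustering agreement metrics
#'
#' Pairwise F-score, BCubed F-score, and normalized mutual information
#' between a predicted and a reference partition of the same element set.
#' All three lie in `[0, 1]`, equal 1 for identical partitions, and are
#' invariant to relabeling of cluster ids.
#'
#' A partition is a named vector: element id -> cluster id.
#'
#' @param pred,truth partitions over identical element sets.
#' @return `pairwise_f()` and `bcubed_f()` return a named numeric vector
#'   `c(precision, recall, f)`; `nmi()` returns a single number.
#' @name clustereval
NULL

check_partitions <- function(pred, truth) {
  pn <- names(pred); tn <- names(truth)
  if (is.null(pn) || is.null(tn)) {
    stop_hiersys("partitions must be named vectors (element id -> cluster id)")
  }
  if (!setequal(pn, tn) || length(pn) != length(tn)) {
    diff <- c(setdiff(pn, tn), setdiff(tn, pn))
    stop_hiersys("partitions cover different elements; symmetric difference: ",
                 paste(head(unique(diff), 10L), collapse = ", "))
  }
  list(pred = as.character(pred[tn]), truth = as.character(truth), n = length(tn))
}

# joint contingency table of two aligned label vectors
contingency <- function(a, b) table(a, b)

#' @rdname clustereval
#' @details `pairwise_f()`: precision is the fraction of same-cluster pairs
#'   of `pred` that are also same-cluster in `truth`; recall swaps the
#'   roles; f is their harmonic mean. If neither partition has any
#'   same-cluster pair (both all-singletons), all three are 1 by
#'   convention, keeping the metric total.
#' @export
pairwise_f <- function(pred, truth) {
  z <- check_partitions(pred, truth)
  ct <- contingency(z$pred, z$truth)
  pairs2 <- function(x) sum(choose(x, 2))
  tp <- pairs2(ct)
  pp <- pairs2(rowSums(ct))
  tt <- pairs2(colSums(ct))
  if (pp == 0 && tt == 0) return(c(precision = 1, recall = 1, f = 1))
  precision <- if (pp > 0) tp / pp else 1
  recall <- if (tt > 0) tp / tt else 1
  f <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  c(precision = precision, recall = recall, f = f)
}

#' @rdname clustereval
#' @details `bcubed_f()`: per element, precision is the fraction of its
#'   predicted cluster that shares its true cluster, recall the fraction of
#'   its true cluster that shares its predicted cluster; both are averaged
#'   over elements before the harmonic mean.
#' @export
bcubed_f <- function(pred, truth) {
  z <- check_partitions(pred, truth)
  ct <- contingency(z$pred, z$truth)
  # element in cell (i,j): precision = ct[i,j]/rowsum_i, recall = ct[i,j]/colsum_j
  rs <- rowSums(ct); cs <- colSums(ct)
  precision <- sum(ct^2 / rs) / z$n
  recall <- sum(t(t(ct^2) / cs)) / z$n
  f <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  c(precision = precision, recall = recall, f = f)
}

#' @rdname clustereval
#' @details `nmi()`: `2 I(U;V) / (H(U) + H(V))` with natural-log entropies
#'   over the joint contingency table; defined as 1 when both partitions
#'   are identical and 0 when `H(U) + H(V) = 0` otherwise (the degenerate
#'   single-cluster-vs-single-cluster case). The arithmetic-mean
#'   normalization keeps the score symmetric.
#' @export
nmi <- function(pred, truth) {
  z <- check_partitions(pred, truth)
  if (identical(unname(relabel(z$pred)), unname(relabel(z$truth)))) return(1)
  ct <- contingency(z$pred, z$truth) / z$n
  hu <- entropy_nat(rowSums(ct))
  hv <- entropy_nat(colSums(ct))
  if (hu + hv == 0) return(0)
  p <- ct[ct > 0]
  pu <- rowSums(ct); pv <- colSums(ct)
  e <- outer(pu, pv)[ct > 0]
  mi <- sum(p * log(p / e))
  max(0, min(1, 2 * mi / (hu + hv)))
}

entropy_nat <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

relabel <- function(x) match(x, unique(x))

#' Flatten a hierarchy at a level and score it against labels
#'
#' Genes are assigned to the system active at the requested level — their
#' deepest ancestor whose level does not exceed `level`; genes with no such
#' ancestor stand as their own singleton cluster. Metrics are computed over
#' `subset` intersected with the labeled genes.
#'
#' @param hierarchy a `hierarchy`.
#' @param labels a `label_partition` (see [flatten_go_labels()]) or a named
#'   vector gene -> class.
#' @param level positive integer level at which to cut the tree.
#' @param subset optional character vector of gene ids to restrict to.
#' @return list with `fp`, `fb`, `nmi`, `n`, `n_clusters_pred`,
#'   `n_clusters_true` plus the per-metric precision/recall.
#' @export
evaluate_hierarchy_level <- function(hierarchy, labels, level, subset = NULL) {
  lab <- if (inherits(labels, "label_partition")) labels$labels else labels
  if (max(hierarchy$systems$level, 0L) < level &&
      nrow(hierarchy$systems) == 0L) {
    # genes-only hierarchy: everyone is a singleton, still evaluable
  }
  pred <- cut_hierarchy(hierarchy, level)
  keep <- intersect(names(pred), names(lab))
  if (!is.null(subset)) keep <- intersect(keep, subset)
  if (length(keep) == 0L) stop_hiersys("no evaluable genes at this level")
  fp <- pairwise_f(pred[keep], lab[keep])
  fb <- bcubed_f(pred[keep], lab[keep])
  list(fp = unname(fp["f"]), fb = unname(fb["f"]),
       nmi = nmi(pred[keep], lab[keep]), n = length(keep),
       n_clusters_pred = length(unique(pred[keep])),
       n_clusters_true = length(unique(lab[keep])),
       pairwise = fp, bcubed = fb)
}

#' Gene partition induced by cutting a hierarchy at a level
#'
#' @inheritParams evaluate_hierarchy_level
#' @return named character vector gene -> cluster id (an ancestor system id,
#'   or the gene itself when it has no ancestor at or below `level`).
#' @export
cut_hierarchy <- function(hierarchy, level) {
  assert_scalar_number(level, "level", lo = 1)
  out <- stats::setNames(hierarchy$genes, hierarchy$genes)
  lev <- stats::setNames(hierarchy$systems$level, hierarchy$systems$id)
  for (g in hierarchy$genes) {
    node <- g
    best <- g
    repeat {
      p <- hierarchy$parent[node]
      if (is.na(p)) break
      if (lev[[p]] <= level) best <- p else break
      node <- p
    }
    out[[g]] <- best
  }
  out
}
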