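#' Hierarchies of gene systems
#'
#' A `hierarchy` is a strict tree over gene leaves: each system groups
#' genes and/or lower systems, each non-root has exactly one parent, levels
#' strictly increase from leaves (level 0) to roots, and every system
#' covers at least two genes. A system's gene set is the union of its
#' children's gene sets.
#'
#' @param genes character vector of gene ids (leaves).
#' @param systems data.frame with columns `id` (character) and `level`
#'   (integer >= 1).
#' @param children named list: for each system id, the character vector of
#'   its direct children (gene or system ids).
#' @return a validated `hierarchy` object.
#' @export
new_hierarchy <- function(genes, systems, children) {
  genes <- sort(unique(as.character(genes)), method = "radix")
  systems <- data.frame(id = as.character(systems$id),
                        level = as.integer(systems$level),
                        stringsAsFactors = FALSE)
  children <- lapply(children, as.character)
  h <- structure(list(genes = genes, systems = systems,
                      children = children[systems$id],
                      parent = derive_parents(children)),
                 class = "hierarchy")
  validate_hierarchy(h)
}

derive_parents <- function(children) {
  kid <- unlist(children, use.names = FALSE)
  par <- rep(names(children), lengths(children))
  if (anyDuplicated(kid)) {
    d <- kid[duplicated(kid)][1L]
    stop_hiersys("node '", d, "' has more than one parent")
  }
  stats::setNames(par, kid)
}

validate_hierarchy <- function(h) {
  sys_ids <- h$systems$id
  if (anyDuplicated(sys_ids)) stop_hiersys("duplicate system ids")
  if (length(intersect(sys_ids, h$genes))) {
    stop_hiersys("ids used both as gene and system: ",
                 intersect(sys_ids, h$genes)[1L])
  }
  lev <- stats::setNames(c(h$systems$level, rep(0L, length(h$genes))),
                         c(sys_ids, h$genes))
  for (s in sys_ids) {
    kids <- h$children[[s]]
    if (is.null(kids) || length(kids) == 0L) {
      stop_hiersys("system '", s, "' has no children")
    }
    unknown <- setdiff(kids, names(lev))
    if (length(unknown)) {
      stop_hiersys("system '", s, "' references unknown child '",
                   unknown[1L], "'")
    }
    if (any(lev[kids] >= lev[s])) {
      bad <- kids[lev[kids] >= lev[s]][1L]
      stop_hiersys("edge ", s, " -> ", bad,
                   ": child level must be below parent level (cycle or ",
                   "inverted edge)")
    }
  }
  gs <- hier_gene_sets(h)
  small <- names(gs)[vapply(gs, length, 1L) < 2L]
  if (length(small)) {
    stop_hiersys("system '", small[1L], "' covers fewer than 2 genes")
  }
  h
}

#' Gene sets of every system
#'
#' @param hierarchy a `hierarchy`.
#' @return named list: system id -> sorted character vector of descendant
#'   gene ids.
#' @export
hier_gene_sets <- function(hierarchy) {
  sys <- hierarchy$systems
  out <- vector("list", nrow(sys))
  names(out) <- sys$id
  for (s in sys$id[order(sys$level)]) {  # children resolved before parents
    kids <- hierarchy$children[[s]]
    g <- kids[kids %in% hierarchy$genes]
    inner <- kids[!kids %in% hierarchy$genes]
    if (length(inner)) g <- c(g, unlist(out[inner], use.names = FALSE))
    out[[s]] <- sort(unique(g), method = "radix")
  }
  out
}

#' Roots of a hierarchy
#' @param hierarchy a `hierarchy`.
#' @return character vector of system (or gene) ids with no parent.
#' @export
hier_roots <- function(hierarchy) {
  all_ids <- c(hierarchy$systems$id, hierarchy$genes)
  setdiff(all_ids, names(hierarchy$parent))
}

#' @export
print.hierarchy <- function(x, ...) {
  cat(sprintf("<hierarchy> %d genes, %d systems, %d levels\n",
              length(x$genes), nrow(x$systems),
              if (nrow(x$systems)) max(x$systems$level) else 0L))
  invisible(x)
}

#' Read / write a hierarchy in 3-column ontology format
#'
#' The interchange format is a headerless tab-delimited file with columns
#' `parent`, `child`, `relation`, where relation is `system` (child is a
#' system) or `gene` (child is a gene leaf) — the convention used by
#' data-driven ontology toolchains. Levels are reconstructed as
#' 1 + the maximum child level. All hierarchy invariants are validated on
#' read; a cycle, a multi-parent node, or an unknown relation is rejected
#' with the offending edge named.
#'
#' @param path path to the ontology file.
#' @return a `hierarchy`.
#' @export
read_ontology <- function(path) {
  if (!file.exists(path)) stop_hiersys("ontology file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("parent", "child", "relation"),
                          colClasses = "character", quote = "")
  bad <- !df$relation %in% c("system", "gene")
  if (any(bad)) {
    i <- which(bad)[1L]
    stop_hiersys("ontology edge ", df$parent[i], " -> ", df$child[i],
                 ": unknown relation '", df$relation[i], "'")
  }
  genes <- unique(df$child[df$relation == "gene"])
  sys_ids <- unique(c(df$parent, df$child[df$relation == "system"]))
  if (length(intersect(genes, sys_ids))) {
    stop_hiersys("id '", intersect(genes, sys_ids)[1L],
                 "' used both as gene and as system")
  }
  children <- split(df$child, factor(df$parent, levels = sys_ids))
  # level assignment by iterative relaxation; failure to converge = cycle
  lev <- stats::setNames(rep(NA_integer_, length(sys_ids)), sys_ids)
  glev <- stats::setNames(rep(0L, length(genes)), genes)
  remaining <- sys_ids
  repeat {
    placed <- FALSE
    for (s in remaining) {
      kl <- c(glev, lev)[children[[s]]]
      if (!anyNA(kl)) {
        lev[s] <- max(kl) + 1L
        placed <- TRUE
      }
    }
    remaining <- names(lev)[is.na(lev)]
    if (length(remaining) == 0L) break
    if (!placed) {
      s <- remaining[1L]
      stop_hiersys("ontology contains a cycle through edge ", s, " -> ",
                   children[[s]][1L])
    }
  }
  new_hierarchy(genes, data.frame(id = sys_ids, level = lev[sys_ids]),
                children)
}

#' @rdname read_ontology
#' @param hierarchy a `hierarchy`.
#' @export
write_ontology <- function(hierarchy, path) {
  rows <- lapply(hierarchy$systems$id, function(s) {
    kids <- hierarchy$children[[s]]
    data.frame(parent = s, child = kids,
               relation = ifelse(kids %in% hierarchy$genes, "gene", "system"),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, c(rows, list(data.frame(parent = character(),
                                               child = character(),
                                               relation = character()))))
  df <- df[order(df$parent, df$child, method = "radix"), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Prune a hierarchy to its significant systems
#'
#' Bottom-up breadth-first pruning: visiting levels from the leaves upward,
#' every system that is neither significant nor a root is removed and its
#' children are re-attached to its parent. Roots are retained regardless of
#' significance so the tree stays connected, and gene leaves are never
#' removed, so the gene complement of every surviving system is unchanged.
#' The operation is idempotent.
#'
#' @param hierarchy a `hierarchy`.
#' @param significant character vector of system ids to keep.
#' @return the pruned `hierarchy`.
#' @export
prune_hierarchy <- function(hierarchy, significant) {
  unknown <- setdiff(significant, hierarchy$systems$id)
  if (length(unknown)) {
    stop_hiersys("unknown system ids in `significant`: ",
                 paste(head(unknown, 5L), collapse = ", "))
  }
  children <- hierarchy$children
  parent <- hierarchy$parent
  sys <- hierarchy$systems
  drop <- character(0)
  for (s in sys$id[order(sys$level)]) {
    if (s %in% significant || !s %in% names(parent)) next
    p <- parent[[s]]
    kids <- children[[s]]
    children[[p]] <- sort(unique(c(setdiff(children[[p]], s), kids)),
                          method = "radix")
    parent[kids] <- p
    parent <- parent[names(parent) != s]
    children[[s]] <- NULL
    drop <- c(drop, s)
  }
  new_hierarchy(hierarchy$genes, sys[!sys$id %in% drop, , drop = FALSE],
                children)
}

#' Export a hierarchy for Cytoscape
#'
#' Writes one SIF line `parent contains child` per parent-child edge, plus
#' a node attribute table (one row per node; first column `id`). Attribute
#' rows keyed by unknown node ids are skipped with a warning.
#'
#' @param hierarchy a `hierarchy`.
#' @param sif_path output path for the SIF file.
#' @param attr_path output path for the attribute TSV.
#' @param node_attributes optional data.frame with an `id` column plus any
#'   attribute columns (e.g. `n_genes`, `S`, `q`, `significant`).
#' @return invisibly, a list with the two paths.
#' @export
export_cytoscape <- function(hierarchy, sif_path, attr_path,
                             node_attributes = NULL) {
  lines <- unlist(lapply(sort(hierarchy$systems$id, method = "radix"),
                         function(s) {
    paste(s, "contains", sort(hierarchy$children[[s]], method = "radix"))
  }))
  writeLines(lines %||% character(0), sif_path)
  known <- c(hierarchy$systems$id, hierarchy$genes)
  if (is.null(node_attributes)) {
    node_attributes <- data.frame(id = character(0))
  }
  if (!"id" %in% names(node_attributes)) {
    stop_hiersys("node_attributes needs an 'id' column")
  }
  bad <- !node_attributes$id %in% known
  if (any(bad)) {
    warning(sum(bad), " attribute row(s) with unknown node ids skipped",
            call. = FALSE)
    node_attributes <- node_attributes[!bad, , drop = FALSE]
  }
  utils::write.table(node_attributes, attr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(sif = sif_path, attributes = attr_path))
}
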