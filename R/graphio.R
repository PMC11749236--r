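#' Read protein sequences from a FASTA file
#'
#' Parses a standard FASTA file into a data frame of protein records. Record
#' order follows the file; sequences are uppercased. The amino-acid alphabet
#' is the 20 standard residues plus the ambiguity/rare codes X, B, Z, U
#' (and *, - which some exporters emit).
#'
#' @param path path to a FASTA file.
#' @return a data.frame of class `protein_records` with columns `id`,
#'   `sequence`, `description` (empty string when the header has no
#'   free-text part).
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 kinase", "MKVLax", ">p2", "ACDE"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_hiersys("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*$", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(structure(
      data.frame(id = character(), sequence = character(),
                 description = character(), stringsAsFactors = FALSE),
      class = c("protein_records", "data.frame")))
  }
  is_header <- startsWith(lines, ">")
  if (!is_header[1L]) {
    stop_hiersys("FASTA parse error at line ", lineno[1L],
                 ": sequence data before any '>' header")
  }
  header_at <- which(is_header)
  ids <- character(length(header_at))
  descs <- character(length(header_at))
  seqs <- character(length(header_at))
  bounds <- c(header_at, length(lines) + 1L)
  for (k in seq_along(header_at)) {
    h <- sub("^>", "", lines[header_at[k]])
    id <- sub("\\s.*$", "", h)
    if (!nzchar(id)) {
      stop_hiersys("FASTA parse error at line ", lineno[header_at[k]],
                   ": empty header")
    }
    body <- lines[seq2(header_at[k] + 1L, bounds[k + 1L] - 1L)]
    sq <- toupper(paste(gsub("\\s", "", body), collapse = ""))
    if (!nzchar(sq)) {
      stop_hiersys("FASTA parse error at line ", lineno[header_at[k]],
                   ": record '", id, "' has an empty sequence")
    }
    bad <- regmatches(sq, regexpr("[^ACDEFGHIKLMNPQRSTVWYXBZU*-]", sq))
    if (length(bad) && nzchar(bad)) {
      stop_hiersys("FASTA parse error at line ", lineno[header_at[k]],
                   ": record '", id, "' contains invalid residue '", bad, "'")
    }
    ids[k] <- id
    descs[k] <- trimws(sub("^\\S+\\s*", "", h))
    seqs[k] <- sq
  }
  if (anyDuplicated(ids)) {
    stop_hiersys("duplicate FASTA ids: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  structure(
    data.frame(id = ids, sequence = seqs, description = descs,
               stringsAsFactors = FALSE),
    class = c("protein_records", "data.frame"))
}

# seq() that yields integer(0) when from > to (unlike base seq)
seq2 <- function(from, to) if (from > to) integer(0) else seq.int(from, to)

#' Read a 5-channel protein association edge table
#'
#' Expects a tab-delimited file with one header row and columns
#' `u`, `v`, `physical`, `mrna_coexp`, `prot_coexp`, `seq_sim`, `codep`.
#' Edges are undirected: rows are canonicalized to `u < v`
#' (lexicographically) and duplicate `(u,v)`/`(v,u)` rows are collapsed by
#' channel-wise maximum, so the strongest evidence per channel survives.
#' Channel scores are kept exactly as read; no rescaling is applied.
#'
#' @param path path to the TSV file.
#' @return a data.frame of class `edge_table` with columns `u`, `v` and the
#'   five channels, sorted by `(u, v)`.
#' @export
read_edge_table <- function(path) {
  if (!file.exists(path)) stop_hiersys("edge table not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1:2),
                          data.table = FALSE, showProgress = FALSE)
  need <- c("u", "v", CHANNELS)
  if (!all(need %in% names(dt))) {
    stop_hiersys("edge table must have columns: ", paste(need, collapse = ", "))
  }
  dt <- dt[need]
  for (ch in CHANNELS) {
    x <- dt[[ch]]
    if (!is.numeric(x)) {
      bad <- which(is.na(suppressWarnings(as.numeric(x))))[1L]
      stop_hiersys("edge table row ", bad, ": non-numeric '", ch, "' score")
    }
    if (anyNA(x) || any(!is.finite(x))) {
      stop_hiersys("edge table row ", which(!is.finite(x))[1L],
                   ": missing or non-finite '", ch, "' score")
    }
    if (any(x < 0)) {
      stop_hiersys("edge table row ", which(x < 0)[1L],
                   ": negative '", ch, "' score")
    }
  }
  as_edge_table(dt)
}

#' Construct/canonicalize an edge table from a data frame
#'
#' @param df data.frame with columns `u`, `v` and the five channel columns.
#' @return canonical `edge_table` (u < v, no duplicates, sorted).
#' @export
as_edge_table <- function(df) {
  u <- as.character(df$u); v <- as.character(df$v)
  if (any(u == v)) {
    stop_hiersys("edge table row ", which(u == v)[1L],
                 ": self-loop '", u[which(u == v)[1L]], "' is not allowed")
  }
  swap <- u > v
  tmp <- u[swap]; u[swap] <- v[swap]; v[swap] <- tmp
  out <- data.frame(u = u, v = v, df[CHANNELS],
                    stringsAsFactors = FALSE, row.names = NULL)
  key <- paste(u, v, sep = "\r")
  if (anyDuplicated(key)) {
    agg <- lapply(out[CHANNELS], function(x) {
      as.numeric(tapply(x, key, max))
    })
    uv <- do.call(rbind, strsplit(sort(unique(key)), "\r", fixed = TRUE))
    out <- data.frame(u = uv[, 1L], v = uv[, 2L], agg,
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$u, out$v, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("edge_table", "data.frame")
  out
}

#' Write an edge table
#'
#' Numeric values are written with up to 12 significant digits so that a
#' write/read round trip is the identity for such values.
#' @param edges an `edge_table`.
#' @param path output path.
#' @export
write_edge_table <- function(edges, path) {
  out <- edges
  for (ch in CHANNELS) out[[ch]] <- fmt_num(out[[ch]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

fmt_num <- function(x) sprintf("%.12g", x)

#' Read a node feature matrix
#'
#' Tab-delimited with a header row: `node_id` then D numeric columns.
#' @param path path to the TSV file.
#' @return numeric matrix with node ids as row names.
#' @export
read_feature_matrix <- function(path) {
  if (!file.exists(path)) stop_hiersys("feature matrix not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1L),
                          data.table = FALSE, showProgress = FALSE)
  if (names(dt)[1L] != "node_id") {
    stop_hiersys("feature matrix must start with a 'node_id' column")
  }
  m <- as.matrix(dt[-1L])
  if (!is.numeric(m) || any(!is.finite(m))) {
    stop_hiersys("feature matrix contains non-numeric or non-finite entries")
  }
  if (ncol(m) < 1L) stop_hiersys("feature matrix needs at least one column")
  if (anyDuplicated(dt$node_id)) stop_hiersys("duplicate node ids in feature matrix")
  rownames(m) <- dt$node_id
  m
}

#' Write a node feature matrix
#' @param features numeric matrix with node ids as row names.
#' @param path output path.
#' @export
write_feature_matrix <- function(features, path) {
  df <- data.frame(node_id = rownames(features),
                   apply(features, 2L, fmt_num),
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (is.null(colnames(features))) {
    names(df)[-1L] <- paste0("f", seq_len(ncol(features)))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble the level-0 affinity graph
#'
#' Joins a canonical edge table with a node feature matrix into the level-0
#' graph consumed by the hierarchical clustering model. Node order is the
#' sorted node-id list of the feature matrix, making all downstream output
#' deterministic.
#'
#' @param edges an `edge_table` (see [read_edge_table()]).
#' @param features numeric matrix, node ids as row names; every edge
#'   endpoint must be present.
#' @return a `level_graph` at level 0.
#' @export
build_affinity_graph <- function(edges, features) {
  ids <- sort(rownames(features), method = "radix")
  missing <- setdiff(unique(c(edges$u, edges$v)), ids)
  if (length(missing)) {
    stop_hiersys("edge endpoints missing from the feature matrix: ",
                 paste(head(missing, 10L), collapse = ", "),
                 if (length(missing) > 10L) ", ...")
  }
  new_level_graph(level = 0L, node_ids = ids,
                  features = features[ids, , drop = FALSE],
                  peak_features = NULL,
                  edges = as.data.frame(edges))
}

new_level_graph <- function(level, node_ids, features, peak_features, edges) {
  rownames(edges) <- NULL
  g <- structure(list(level = as.integer(level), node_ids = node_ids,
                      features = features, peak_features = peak_features,
                      edges = edges),
                 class = "level_graph")
  validate_level_graph(g)
}

validate_level_graph <- function(g) {
  stopifnot(is.matrix(g$features),
            identical(rownames(g$features), g$node_ids))
  if (any(!is.finite(g$features))) stop_hiersys("non-finite node features")
  known <- c(g$edges$u, g$edges$v) %in% g$node_ids
  if (!all(known)) stop_hiersys("edge endpoint not among graph nodes")
  want <- if (g$level == 0L) CHANNELS else "weight"
  if (nrow(g$edges) > 0L && !all(want %in% names(g$edges))) {
    stop_hiersys("level-", g$level, " graph edges must carry: ",
                 paste(want, collapse = ", "))
  }
  g
}

#' @export
print.level_graph <- function(x, ...) {
  cat(sprintf("<level_graph> level %d: %d nodes, %d edges, %d features/node\n",
              x$level, length(x$node_ids), nrow(x$edges), ncol(x$features)))
  invisible(x)
}

#' Connected components of a level graph
#'
#' @param graph a `level_graph`.
#' @param edge_subset optional data.frame (columns `u`, `v`) restricting the
#'   edge set; must be a subset of the graph's edges.
#' @return named character vector: for every node, the id of its component,
#'   defined as the lexicographically smallest member id (deterministic).
#' @export
connected_components <- function(graph, edge_subset = NULL) {
  ed <- if (is.null(edge_subset)) graph$edges else as.data.frame(edge_subset)
  if (!is.null(edge_subset) && nrow(ed) > 0L) {
    have <- paste(graph$edges$u, graph$edges$v)
    ask <- paste(pmin(ed$u, ed$v), pmax(ed$u, ed$v))
    if (!all(ask %in% have)) stop_hiersys("edge_subset contains unknown edges")
  }
  comp_of_edges(graph$node_ids, ed)
}

# components from an explicit node list + edge pairs (igraph-backed)
comp_of_edges <- function(node_ids, edges) {
  if (length(node_ids) == 0L) return(stats::setNames(character(0), character(0)))
  g <- igraph::graph_from_data_frame(
    d = if (nrow(edges)) edges[, c("u", "v")] else data.frame(u = character(), v = character()),
    directed = FALSE,
    vertices = data.frame(name = node_ids))
  m <- igraph::components(g)$membership
  comp_min <- tapply(names(m), m, function(ids) min(ids))
  stats::setNames(as.character(comp_min[as.character(m[node_ids])]), node_ids)
}
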