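#' Flatten multi-label GO annotations into single-class supervision
#'
#' GO annotation is many-to-many; the clustering model needs one class per
#' gene. Terms whose member count falls outside `[min_size, max_size]` are
#' discarded (huge terms are uninformative, tiny ones unlearnable), and
#' each gene is assigned its smallest surviving term — the most specific
#' annotation it has — with ties broken by term id. Genes with no
#' surviving term are excluded from the partition.
#'
#' @param annotations either a data.frame with columns `gene` and `term`,
#'   or a named list gene id -> character vector of term ids.
#' @param branch label source tag, one of `"BP"`, `"CC"`, `"MF"`, `"GO"`.
#' @param min_size,max_size surviving-term size window (defaults 10, 500).
#' @return a `label_partition`: list with `labels` (named vector gene ->
#'   class/term id), `branch`, `class_sizes`.
#' @export
flatten_go_labels <- function(annotations, branch = c("GO", "BP", "CC", "MF"),
                              min_size = 10L, max_size = 500L) {
  branch <- match.arg(branch)
  if (is.data.frame(annotations)) {
    df <- data.frame(gene = as.character(annotations$gene),
                     term = as.character(annotations$term),
                     stringsAsFactors = FALSE)
  } else {
    if (length(annotations) == 0L) stop_hiersys("annotations are empty")
    df <- data.frame(gene = rep(names(annotations), lengths(annotations)),
                     term = unlist(annotations, use.names = FALSE),
                     stringsAsFactors = FALSE)
  }
  if (nrow(df) == 0L) stop_hiersys("annotations are empty")
  df <- unique(df)
  sizes <- table(df$term)
  ok <- names(sizes)[sizes >= min_size & sizes <= max_size]
  if (length(ok) == 0L) {
    stop_hiersys("no GO term has between ", min_size, " and ", max_size,
                 " member genes; widen the size window")
  }
  df <- df[df$term %in% ok, , drop = FALSE]
  df$size <- as.integer(sizes[df$term])
  df <- df[order(df$gene, df$size, df$term, method = "radix"), , drop = FALSE]
  df <- df[!duplicated(df$gene), , drop = FALSE]
  labels <- stats::setNames(df$term, df$gene)
  new_label_partition(labels, branch)
}

new_label_partition <- function(labels, branch = "GO") {
  if (is.null(names(labels)) || anyDuplicated(names(labels))) {
    stop_hiersys("labels must be uniquely named by gene id")
  }
  labels <- labels[sort(names(labels), method = "radix")]
  structure(list(labels = stats::setNames(as.character(labels), names(labels)),
                 branch = branch,
                 class_sizes = table(as.character(labels))),
            class = "label_partition")
}

#' @export
print.label_partition <- function(x, ...) {
  cat(sprintf("<label_partition> %s: %d genes in %d classes\n",
              x$branch, length(x$labels), length(x$class_sizes)))
  invisible(x)
}

#' Read gene -> GO annotations from TSV
#'
#' Two tab-delimited columns with header `gene`, `term`.
#' @param path TSV path.
#' @return data.frame with columns `gene`, `term`.
#' @export
read_annotations <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character", data.table = FALSE,
                          showProgress = FALSE)
  if (!all(c("gene", "term") %in% names(df))) {
    stop_hiersys("annotation file must have columns gene, term")
  }
  df[c("gene", "term")]
}

#' Split node ids into train / validation / test sets
#'
#' Sizes are the rounded ratio shares of n (train and validation rounded,
#' test takes the remainder); the assignment is a seeded uniform shuffle,
#' so the three sets are disjoint, cover the input, and are reproducible.
#'
#' @param node_ids character vector (at least 3 ids).
#' @param ratios numeric length-3 `(train, val, test)`, positive, summing
#'   to 1; default the conventional 70:10:20.
#' @param seed integer seed.
#' @return list with character vectors `train`, `val`, `test`.
#' @export
split_nodes <- function(node_ids, ratios = c(0.7, 0.1, 0.2), seed = 1L) {
  n <- length(node_ids)
  if (n < 3L) stop_hiersys("need at least 3 nodes to split")
  if (length(ratios) != 3L || any(ratios <= 0) ||
      abs(sum(ratios) - 1) > 1e-9) {
    stop_hiersys("ratios must be 3 positive numbers summing to 1")
  }
  n_train <- round(n * ratios[1L])
  n_val <- round(n * ratios[2L])
  if (n_train + n_val >= n) {  # degenerate rounding on tiny n
    n_train <- max(1L, n - 2L); n_val <- 1L
  }
  perm <- with_seed(seed, sample(node_ids))
  list(train = perm[seq_len(n_train)],
       val = perm[seq2(n_train + 1L, n_train + n_val)],
       test = perm[seq2(n_train + n_val + 1L, n)])
}
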