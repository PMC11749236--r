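# Independent oracles, deliberately naive: brute-force enumeration and
# textbook algorithms, sharing no code with the implementation they check.

# --- union-find components -------------------------------------------------
uf_components <- function(ids, edges) {
  parent <- stats::setNames(ids, ids)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      ru <- find(edges$u[r]); rv <- find(edges$v[r])
      if (ru != rv) parent[[ru]] <- rv
    }
  }
  roots <- vapply(ids, find, "")
  comp_min <- tapply(ids, roots, min)
  stats::setNames(as.character(comp_min[roots]), ids)
}

# --- clustering metrics by enumeration ------------------------------------
bf_pairwise <- function(pred, truth) {
  ids <- names(truth)
  pred <- pred[ids]
  tp <- fp <- fn <- 0
  n <- length(ids)
  for (i in seq2(1L, n - 1L)) {
    for (j in seq2(i + 1L, n)) {
      sp <- pred[i] == pred[j]; st <- truth[i] == truth[j]
      tp <- tp + (sp && st); fp <- fp + (sp && !st); fn <- fn + (!sp && st)
    }
  }
  if (tp + fp == 0 && tp + fn == 0) return(c(precision = 1, recall = 1, f = 1))
  pr <- if (tp + fp > 0) tp / (tp + fp) else 1
  rc <- if (tp + fn > 0) tp / (tp + fn) else 1
  f <- if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
  c(precision = pr, recall = rc, f = f)
}

bf_bcubed <- function(pred, truth) {
  ids <- names(truth)
  pred <- pred[ids]
  pr <- rc <- numeric(length(ids))
  for (k in seq_along(ids)) {
    pc <- ids[pred == pred[k]]
    tc <- ids[truth == truth[k]]
    pr[k] <- mean(truth[pc] == truth[k])
    rc[k] <- mean(pred[tc] == pred[k])
  }
  p <- mean(pr); r <- mean(rc)
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f = f)
}

bf_nmi <- function(pred, truth) {
  ids <- names(truth)
  a <- as.character(pred[ids]); b <- as.character(truth)
  n <- length(ids)
  mi <- 0
  for (ca in unique(a)) {
    for (cb in unique(b)) {
      nij <- sum(a == ca & b == cb)
      if (nij > 0) {
        mi <- mi + (nij / n) * log((nij / n) / ((sum(a == ca) / n) *
                                                  (sum(b == cb) / n)))
      }
    }
  }
  ent <- function(x) {
    p <- table(x) / length(x)
    -sum(p * log(p))
  }
  denom <- ent(a) + ent(b)
  if (denom == 0) return(if (identical(match(a, unique(a)),
                                       match(b, unique(b)))) 1 else 0)
  2 * mi / denom
}

seq2 <- function(from, to) if (from > to) integer(0) else seq.int(from, to)

random_partition <- function(n, kmax = 6L) {
  stats::setNames(as.character(sample.int(kmax, n, replace = TRUE)),
                  sprintf("e%02d", seq_len(n)))
}

# --- nonnegative lasso QP oracle: projected gradient ----------------------
nnlasso_objective <- function(y, X, beta, lambda) {
  r <- y - as.vector(X %*% beta)
  sum(r^2) / (2 * length(y)) + lambda * sum(beta)
}

pg_nnlasso <- function(y, X, lambda, iters = 50000L) {
  n <- length(y)
  G <- crossprod(X) / n
  L <- max(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  beta <- rep(0, ncol(X))
  xty <- crossprod(X, y) / n
  for (it in seq_len(iters)) {
    grad <- as.vector(G %*% beta) - as.vector(xty) + lambda
    beta_new <- pmax(0, beta - grad / L)
    if (max(abs(beta_new - beta)) < 1e-12) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  beta
}

# --- small fixture builders -----------------------------------------------
toy_edges <- function(u, v, score = 0.5) {
  score <- rep_len(score, length(u))
  data.frame(u = u, v = v, physical = score, mrna_coexp = score,
             prot_coexp = score, seq_sim = score, codep = score,
             stringsAsFactors = FALSE)
}

toy_graph0 <- function(n = 4L, edges = NULL, D = 3L, seed = 1L) {
  ids <- sprintf("n%d", seq_len(n))
  feats <- withr::with_seed(seed, matrix(rnorm(n * D), n,
                                         dimnames = list(ids, NULL)))
  if (is.null(edges)) edges <- toy_edges(character(0), character(0))
  build_affinity_graph(as_edge_table(edges), feats)
}

toy_hierarchy <- function() {
  # root R1 (level 2) over s1 = {g1, g2} (level 1) and g3
  new_hierarchy(
    genes = c("g1", "g2", "g3"),
    systems = data.frame(id = c("s1", "R1"), level = c(1L, 2L)),
    children = list(s1 = c("g1", "g2"), R1 = c("s1", "g3")))
}

random_hierarchy <- function(n_genes = 12L, n_sys = 4L) {
  n_sys <- min(n_sys, n_genes %/% 2L)  # leaf systems need >= 2 genes each
  genes <- sprintf("g%02d", seq_len(n_genes))
  # random binary-ish tree: genes partitioned into n_sys leaf systems of
  # >= 2 genes, plus one root over all systems
  repeat {
    cut <- sort(sample.int(n_genes - 1L, n_sys - 1L))
    sizes <- diff(c(0L, cut, n_genes))
    if (all(sizes >= 2L)) break
  }
  idx <- rep(seq_len(n_sys), sizes)
  children <- split(genes, idx)
  names(children) <- sprintf("s%02d", seq_len(n_sys))
  children$root <- names(children)
  new_hierarchy(genes,
                data.frame(id = c(sprintf("s%02d", seq_len(n_sys)), "root"),
                           level = c(rep(1L, n_sys), 2L)),
                children)
}
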