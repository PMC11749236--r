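#' Gene-level signal tracks
#'
#' A signal track is a nonnegative per-gene response `y` for the
#' selective-pressure regression: corrected mutation counts, a
#' meta-survival z combination, perturbation amplitudes, or dependency
#' scores. Signed tracks must declare a rectifying transform (`"abs"` or
#' `"relu"`); after the transform every value is required to be
#' nonnegative and finite.
#'
#' @param name track label.
#' @param values named numeric vector, gene id -> value.
#' @param transform one of `"none"`, `"abs"`, `"relu"`, applied lazily by
#'   [run_hisig()]/[lasso_path()].
#' @return a `signal_track` object.
#' @export
signal_track <- function(name, values, transform = c("none", "abs", "relu")) {
  transform <- match.arg(transform)
  if (is.null(names(values)) || anyDuplicated(names(values))) {
    stop_hiersys("signal values must be uniquely named by gene id")
  }
  if (any(!is.finite(values))) stop_hiersys("non-finite signal values")
  structure(list(name = name, values = values, transform = transform),
            class = "signal_track")
}

apply_transform <- function(track) {
  v <- switch(track$transform,
              none = track$values,
              abs = abs(track$values),
              relu = pmax(track$values, 0))
  if (any(v < 0)) {
    stop_hiersys("track '", track$name, "' has negative values after ",
                 "transform '", track$transform, "'; use transform = 'abs' ",
                 "or 'relu' for signed tracks")
  }
  v
}

#' Read a gene-level signal track from TSV
#'
#' Expects a header row with columns `gene_id` and `value`.
#' @param path TSV path.
#' @inheritParams signal_track
#' @return a `signal_track`.
#' @export
read_signal_track <- function(path, name = basename(path),
                              transform = "none") {
  df <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1L),
                          data.table = FALSE, showProgress = FALSE)
  if (!all(c("gene_id", "value") %in% names(df))) {
    stop_hiersys("signal file must have columns gene_id, value")
  }
  signal_track(name, stats::setNames(as.numeric(df$value), df$gene_id),
               transform)
}

#' Combine per-platform survival z-scores into a meta z-score
#'
#' For gene g with z-scores over K_g non-missing platforms,
#' `z_meta(g) = sum_i Z_i(g) / sqrt(K_g)` — the Stouffer combination that
#' keeps a standard-normal null regardless of platform count. Genes with
#' all platforms missing are excluded with a warning.
#'
#' @param ztable data.frame: `gene_id` column plus one numeric column per
#'   platform (typically CNV, expression, methylation, mutation); `NA`
#'   marks a missing platform measurement.
#' @param transform transform tag for the resulting track (meta-z is
#'   signed, so `"abs"` by default).
#' @return a `signal_track` named `"meta_z"`.
#' @export
meta_z <- function(ztable, transform = "abs") {
  if (!"gene_id" %in% names(ztable)) {
    stop_hiersys("ztable needs a gene_id column")
  }
  z <- as.matrix(ztable[setdiff(names(ztable), "gene_id")])
  if (!is.numeric(z) || ncol(z) < 1L) {
    stop_hiersys("ztable needs at least one numeric platform column")
  }
  k <- rowSums(!is.na(z))
  if (any(k == 0L)) {
    warning(sum(k == 0L), " gene(s) with all platforms missing excluded",
            call. = FALSE)
  }
  keep <- k > 0L
  vals <- rowSums(z, na.rm = TRUE)[keep] / sqrt(k[keep])
  signal_track("meta_z", stats::setNames(vals, ztable$gene_id[keep]),
               transform)
}

#' Read a per-platform z-score table
#'
#' Tab-delimited with a header: `gene_id` followed by one numeric column
#' per platform; empty cells / NA mark missing platform measurements.
#' Feed the result to [meta_z()].
#' @param path TSV path.
#' @return data.frame with `gene_id` and platform columns.
#' @export
read_ztable <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1L),
                          data.table = FALSE, showProgress = FALSE)
  if (names(df)[1L] != "gene_id" || ncol(df) < 2L) {
    stop_hiersys("ztable must have a gene_id column plus platform columns")
  }
  df
}

#' Binary gene-by-system membership matrix
#'
#' Column `c` has a 1 exactly for the genes in system `c`'s descendant
#' gene set; nested systems therefore give entrywise-ordered columns.
#'
#' @param hierarchy a `hierarchy`.
#' @return a sparse 0/1 `Matrix` (genes x systems) with dimnames; zero
#'   columns are impossible, zero systems give a 0-column matrix.
#' @export
membership_matrix <- function(hierarchy) {
  gs <- hier_gene_sets(hierarchy)
  genes <- hierarchy$genes
  p <- length(gs)
  i <- as.integer(unlist(lapply(gs, function(g) match(g, genes)),
                         use.names = FALSE))
  j <- rep(seq_len(p), vapply(gs, length, 1L))
  Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(length(genes), p),
                       dimnames = list(genes, names(gs)))
}

members_list <- function(H) {
  if (!methods::is(H, "sparseMatrix")) H <- Matrix::Matrix(H, sparse = TRUE)
  H <- methods::as(H, "CsparseMatrix")
  p <- ncol(H)
  lapply(seq_len(p), function(c) {
    H@i[seq2(H@p[c] + 1L, H@p[c + 1L])]  # 0-based row indices
  })
}

#' Nonnegative lasso path over the gene + system design
#'
#' Solves, for each lambda on a descending log-spaced grid,
#' `min (1/(2n)) ||y - I w - H v||^2 + lambda (sum(w) + sum(v))` with
#' `w, v >= 0`: the per-gene weights `w` compete with the per-system
#' weights `v` to explain the signal, and a system only earns weight when
#' its genes share elevated signal beyond what individual gene terms buy.
#' `lambda_max` (the smallest lambda with an all-zero solution) is
#' `max_j X_j' y / n`; the grid runs from there down to
#' `lambda_max * lambda_min_ratio`. Columns are not standardized. The
#' solver is coordinate descent with warm starts; the KKT residual at
#' every grid point is returned and is required to be tiny.
#'
#' @param y a `signal_track` or a named nonnegative numeric vector.
#' @param H membership matrix (genes x systems) with dimnames, as from
#'   [membership_matrix()].
#' @param n_lambda number of grid points (default 500).
#' @param lambda_min_ratio grid floor relative to `lambda_max`.
#' @param tol KKT tolerance.
#' @return a `hisig_path`: list with `lambdas`, `W` (genes x L), `V`
#'   (systems x L), `kkt`, and `all_zero` flag (TRUE when `y` is all
#'   zero, in which case the whole path is zero).
#' @export
lasso_path <- function(y, H, n_lambda = 500L, lambda_min_ratio = 1e-3,
                       tol = 1e-9) {
  yv <- align_signal(y, rownames(H))
  mem <- members_list(H)
  lam <- lambda_grid(yv, mem, n_lambda, lambda_min_ratio)
  fit <- .nnlasso_path_cpp(unname(yv), mem, lam$lambdas, tol = tol)
  dimnames(fit$W) <- list(rownames(H), NULL)
  dimnames(fit$V) <- list(colnames(H), NULL)
  structure(list(lambdas = lam$lambdas, W = fit$W, V = fit$V,
                 kkt = fit$kkt, all_zero = lam$all_zero),
            class = "hisig_path")
}

align_signal <- function(y, genes) {
  if (inherits(y, "signal_track")) y <- apply_transform(y)
  if (is.null(names(y))) stop_hiersys("signal must be named by gene id")
  if (any(y < 0)) stop_hiersys("signal must be nonnegative (apply a transform)")
  missing <- setdiff(genes, names(y))
  if (length(missing)) {
    warning(length(missing), " hierarchy gene(s) missing from the signal; ",
            "set to 0", call. = FALSE)
  }
  out <- stats::setNames(rep(0, length(genes)), genes)
  out[intersect(names(y), genes)] <- y[intersect(names(y), genes)]
  out
}

lambda_grid <- function(yv, mem, n_lambda, lambda_min_ratio) {
  n <- length(yv)
  corr <- c(yv, vapply(mem, function(m) sum(yv[m + 1L]), 0)) / n
  lambda_max <- max(corr, 0)
  all_zero <- lambda_max <= 0
  if (all_zero) lambda_max <- 1  # arbitrary; solutions are zero throughout
  list(lambdas = exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                         length.out = n_lambda)),
       all_zero = all_zero)
}

#' Selective pressure of each system along a lasso path
#'
#' `S(c)` is the maximum, over lambdas with positive total weight, of
#' system c's share of all weight:
#' `v_c(lambda) / (sum_c' v_c'(lambda) + sum_g w_g(lambda))`. Grid points
#' with zero total weight are skipped; a system that is never active gets
#' `S(c) = 0`. Shares at any lambda sum to 1 over systems plus genes, so
#' `S(c)` always lies in `[0, 1]`.
#'
#' @param path a `hisig_path`.
#' @return named numeric vector, system id -> S.
#' @export
selective_pressure <- function(path) {
  total <- colSums(path$W) + colSums(path$V)
  ok <- total > 1e-12
  p <- nrow(path$V)
  if (!any(ok) || p == 0L) {
    return(stats::setNames(rep(0, p), rownames(path$V)))
  }
  frac <- path$V[, ok, drop = FALSE] / rep(total[ok], each = p)
  stats::setNames(apply(frac, 1L, max), rownames(path$V))
}

#' Permutation p-values for selective pressure
#'
#' The rows of `H` are permuted with respect to gene labels (whole rows,
#' so every system keeps its size), the full lasso path and `S` are
#' recomputed for each permutation, and
#' `p(c) = (1 + #\{S_perm(c) >= S_obs(c)\}) / (1 + n_perm)` — the add-one
#' correction keeps p strictly positive.
#'
#' @inheritParams lasso_path
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed for the permutation stream.
#' @param s_obs optional precomputed observed `S` (skips one path solve).
#' @return list with `p` (named per system), `S` observed, `n_perm`.
#' @export
permutation_pvalues <- function(y, H, n_perm = 10000L, seed = 1L,
                                n_lambda = 500L, lambda_min_ratio = 1e-3,
                                tol = 1e-9, s_obs = NULL) {
  if (length(n_perm) != 1L || is.na(n_perm) || n_perm < 0) {
    stop_hiersys("n_perm must be a nonnegative integer")
  }
  yv <- align_signal(y, rownames(H))
  mem <- members_list(H)
  lam <- lambda_grid(yv, mem, n_lambda, lambda_min_ratio)
  if (is.null(s_obs)) {
    s_obs <- stats::setNames(
      .hisig_S_cpp(unname(yv), mem, lam$lambdas, tol = tol), colnames(H))
  }
  n <- length(yv)
  if (n_perm == 0L) {
    p <- stats::setNames(rep(1, ncol(H)), colnames(H))
    return(list(p = p, S = s_obs, n_perm = 0L))
  }
  perms <- with_seed(seed, {
    matrix(unlist(lapply(seq_len(n_perm), function(k) sample.int(n) - 1L)),
           nrow = n)
  })
  s_perm <- .hisig_perm_S_cpp(unname(yv), mem, lam$lambdas, perms, tol = tol)
  exceed <- colSums(s_perm >= rep(s_obs[colnames(H)], each = n_perm))
  p <- stats::setNames((1 + exceed) / (1 + n_perm), colnames(H))
  list(p = p, S = s_obs, n_perm = as.integer(n_perm))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment with monotonicity enforcement;
#' order-preserving and capped at 1.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return q-values in the input order (names preserved).
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop_hiersys("p-values must lie in (0, 1]")
  }
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(p[o] * m / seq(m, 1)))
  out <- numeric(m)
  out[o] <- q
  names(out) <- names(p)
  out
}

#' Run the full selective-pressure analysis for one signal track
#'
#' Composes transform, lasso path, selective pressure, permutation
#' p-values, and BH adjustment; a system is a clinical hotspot when its
#' q-value falls below `fdr_cutoff` (0.25 by convention for this screen).
#' Fully reproducible from (inputs, config, seed).
#'
#' @param track a `signal_track`.
#' @param hierarchy a `hierarchy`.
#' @param n_lambda,lambda_min_ratio,tol see [lasso_path()].
#' @param n_perm,seed see [permutation_pvalues()].
#' @param fdr_cutoff FDR threshold for the `significant` flag.
#' @return a `hisig_result` data.frame with columns `system_id`, `n_genes`,
#'   `S`, `p`, `q`, `significant`, ordered by q then S; run metadata in
#'   attributes `track`, `n_perm`, `seed`, `fdr_cutoff`, `all_zero`.
#' @export
run_hisig <- function(track, hierarchy, n_lambda = 500L,
                      lambda_min_ratio = 1e-3, n_perm = 10000L, seed = 1L,
                      fdr_cutoff = 0.25, tol = 1e-9) {
  stopifnot(inherits(track, "signal_track"), inherits(hierarchy, "hierarchy"))
  H <- membership_matrix(hierarchy)
  extra <- setdiff(names(track$values), hierarchy$genes)
  if (length(extra)) {
    warning(length(extra), " track gene(s) not in the hierarchy ignored",
            call. = FALSE)
  }
  yv <- align_signal(track, rownames(H))
  perm <- permutation_pvalues(yv, H, n_perm = n_perm, seed = seed,
                              n_lambda = n_lambda,
                              lambda_min_ratio = lambda_min_ratio, tol = tol)
  q <- bh_adjust(perm$p)
  n_genes <- vapply(hier_gene_sets(hierarchy), length, 1L)
  res <- data.frame(system_id = colnames(H),
                    n_genes = unname(n_genes[colnames(H)]),
                    S = unname(perm$S[colnames(H)]),
                    p = unname(perm$p[colnames(H)]),
                    q = unname(q[colnames(H)]),
                    significant = unname(q[colnames(H)] < fdr_cutoff),
                    stringsAsFactors = FALSE)
  res <- res[order(res$q, -res$S, res$system_id, method = "radix"), ,
             drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("hisig_result", "data.frame"),
            track = track$name, n_perm = as.integer(n_perm),
            seed = as.integer(seed), fdr_cutoff = fdr_cutoff,
            all_zero = all(yv == 0))
}

#' Write / read a hisig result table
#' @param result a `hisig_result`.
#' @param path TSV path.
#' @export
write_hisig_result <- function(result, path) {
  out <- result
  for (cl in c("S", "p", "q")) out[[cl]] <- fmt_num(out[[cl]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hisig_result
#' @export
read_hisig_result <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE, showProgress = FALSE)
  df$significant <- as.logical(df$significant)
  structure(df, class = c("hisig_result", "data.frame"))
}

#' Intersect clinical hotspots across signal tracks
#'
#' @param ... two or more `hisig_result` tables computed on the same
#'   hierarchy (identical system-id sets).
#' @return data.frame with `system_id` (the intersection of the significant
#'   sets) and one q-value column per track.
#' @export
intersect_hotspots <- function(...) {
  results <- list(...)
  if (length(results) == 1L && is.list(results[[1]]) &&
      !inherits(results[[1]], "data.frame")) {
    results <- results[[1]]
  }
  if (length(results) < 2L) stop_hiersys("need at least two result tables")
  ids <- lapply(results, function(r) sort(r$system_id))
  for (k in seq_along(results)[-1L]) {
    if (!identical(ids[[1L]], ids[[k]])) {
      stop_hiersys("result tables cover different hierarchies")
    }
  }
  common <- Reduce(intersect,
                   lapply(results, function(r) r$system_id[r$significant]))
  common <- sort(common, method = "radix")
  out <- data.frame(system_id = common, stringsAsFactors = FALSE)
  for (k in seq_along(results)) {
    nm <- attr(results[[k]], "track") %||% paste0("track", k)
    out[[paste0("q_", nm)]] <-
      results[[k]]$q[match(common, results[[k]]$system_id)]
  }
  out
}
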