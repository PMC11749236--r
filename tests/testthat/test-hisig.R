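test_that("meta_z follows the Stouffer closed form and is linear", {
  zt <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                   cnv = c(0, 1, 1.2, NA), expr = c(0, 1, -0.5, NA),
                   meth = c(0, 1, 2.0, NA), mut = c(0, 1, 0.3, NA))
  tr <- suppressWarnings(meta_z(zt, transform = "none"))
  expect_equal(unname(tr$values["g1"]), 0)
  expect_equal(unname(tr$values["g2"]), 2)          # 4 / sqrt(4)
  expect_equal(unname(tr$values["g3"]), 3.0 / 2)    # closed form
  expect_false("g4" %in% names(tr$values))
  expect_warning(meta_z(zt), "all platforms missing")

  # missing platforms use K_g, not K
  zt2 <- data.frame(gene_id = "g1", a = 2, b = NA)
  expect_equal(unname(suppressWarnings(meta_z(zt2))$values), 2 / sqrt(1))

  # linearity in a common scaling
  z3 <- data.frame(gene_id = c("a", "b"), p1 = c(1.5, -2), p2 = c(0.5, 1))
  t1 <- meta_z(z3, transform = "none")
  z3[2:3] <- z3[2:3] * 3
  expect_equal(meta_z(z3, transform = "none")$values, 3 * t1$values)
})

test_that("ztable files round-trip into meta_z", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tcnv\texpr", "g1\t1\t1", "g2\t2\tNA"), f)
  zt <- read_ztable(f)
  tr <- meta_z(zt, transform = "none")
  expect_equal(unname(tr$values), c(2 / sqrt(2), 2))
  writeLines("gene\tcnv", f)
  expect_error(read_ztable(f), "gene_id")
})

test_that("membership matrix encodes descendant gene sets with nesting", {
  h <- toy_hierarchy()
  H <- membership_matrix(h)
  expect_equal(dim(H), c(3L, 2L))
  expect_equal(unname(Matrix::colSums(H)[c("s1", "R1")]), c(2, 3))
  expect_true(all(H[, "s1"] <= H[, "R1"]))  # child <= parent entrywise

  genes_only <- new_hierarchy(c("g1", "g2"),
                              data.frame(id = character(),
                                         level = integer()), list())
  expect_equal(ncol(membership_matrix(genes_only)), 0L)
})

test_that("the analytic single-system lasso path is exact", {
  h <- new_hierarchy(c("g1", "g2"),
                     data.frame(id = "s1", level = 1L),
                     list(s1 = c("g1", "g2")))
  H <- membership_matrix(h)
  y <- c(g1 = 2, g2 = 2)
  path <- lasso_path(y, H, n_lambda = 60, lambda_min_ratio = 1e-3)
  expect_equal(path$lambdas[1], 2)                      # lambda_max
  expect_equal(unname(path$V[1, ]), pmax(0, 2 - path$lambdas),
               tolerance = 1e-8)
  expect_true(all(path$W == 0))
  expect_true(all(path$V[, 1] == 0))                    # zero at lambda_max
  expect_lt(max(path$kkt), 1e-8)
})

test_that("zero signal yields a flagged all-zero path", {
  h <- toy_hierarchy()
  p0 <- lasso_path(c(g1 = 0, g2 = 0, g3 = 0), membership_matrix(h),
                   n_lambda = 10)
  expect_true(p0$all_zero)
  expect_true(all(p0$W == 0) && all(p0$V == 0))
  expect_equal(unname(selective_pressure(p0)), c(0, 0))
})

test_that("path objective matches a projected-gradient QP oracle", {
  withr::local_seed(20)
  for (case in 1:20) {
    n <- sample(4:10, 1)
    p <- sample(1:4, 1)
    genes <- sprintf("g%02d", seq_len(n))
    mem <- lapply(seq_len(p), function(c) sort(sample(genes,
                                                      sample(2:n, 1))))
    Hd <- sapply(mem, function(m) as.numeric(genes %in% m))
    dimnames(Hd) <- list(genes, sprintf("s%d", seq_len(p)))
    y <- stats::setNames(round(abs(rnorm(n, 1, 1)), 3), genes)
    path <- lasso_path(y, Hd, n_lambda = 10, lambda_min_ratio = 0.05)
    X <- cbind(diag(n), Hd)
    for (l in seq_along(path$lambdas)) {
      beta_hat <- c(path$W[, l], path$V[, l])
      beta_orc <- pg_nnlasso(unname(y), X, path$lambdas[l])
      expect_lte(nnlasso_objective(unname(y), X, beta_hat, path$lambdas[l]),
                 nnlasso_objective(unname(y), X, beta_orc,
                                   path$lambdas[l]) + 1e-6)
      expect_true(all(beta_hat >= 0))
    }
  }
})

test_that("selective pressure is a conserved max weight fraction", {
  # two-lambda toy path checked by direct enumeration
  path <- structure(list(
    lambdas = c(1, 0.5),
    W = matrix(c(0, 0, 0.25, 0.25), 2, 2,
               dimnames = list(c("g1", "g2"), NULL)),
    V = matrix(c(0.5, 0, 0.25, 0.25), 2, 2,
               dimnames = list(c("c1", "c2"), NULL)),
    kkt = c(0, 0), all_zero = FALSE), class = "hisig_path")
  S <- selective_pressure(path)
  expect_equal(unname(S), c(1.0, 0.25))

  # fraction conservation on a real fit
  d <- simulate_dataset(synthetic_spec(n_genes = 60, branching = c(6, 2),
                                       seed = 3))
  pth <- lasso_path(d$tracks$counts, membership_matrix(d$hierarchy),
                    n_lambda = 40)
  tot <- colSums(pth$W) + colSums(pth$V)
  ok <- tot > 1e-12
  frac_sum <- (colSums(pth$W)[ok] + colSums(pth$V)[ok]) / tot[ok]
  expect_equal(unname(frac_sum), rep(1, sum(ok)), tolerance = 1e-12)
  Sr <- selective_pressure(pth)
  expect_true(all(Sr >= 0 & Sr <= 1))
})

test_that("permutation p-values honor add-one and invariance conventions", {
  h <- toy_hierarchy()
  H <- membership_matrix(h)
  y <- c(g1 = 3, g2 = 2.5, g3 = 0.1)
  p0 <- permutation_pvalues(y, H, n_perm = 0, seed = 1, n_lambda = 20)
  expect_equal(unname(p0$p), c(1, 1))

  # constant y: every permutation gives the identical path, so p = 1
  yc <- c(g1 = 1, g2 = 1, g3 = 1)
  pc <- permutation_pvalues(yc, H, n_perm = 25, seed = 2, n_lambda = 20)
  expect_equal(unname(pc$p), c(1, 1))

  expect_error(permutation_pvalues(y, H, n_perm = -1), "nonnegative")

  # determinism
  pa <- permutation_pvalues(y, H, n_perm = 30, seed = 7, n_lambda = 20)
  pb <- permutation_pvalues(y, H, n_perm = 30, seed = 7, n_lambda = 20)
  expect_identical(pa, pb)
})

test_that("a strongly burdened system attains the minimum attainable p", {
  d <- simulate_dataset(synthetic_spec(n_genes = 150, branching = c(15, 3),
                                       planted_systems = 1, effect_size = 6,
                                       seed = 1))
  H <- membership_matrix(d$hierarchy)
  pp <- permutation_pvalues(d$tracks$zscores, H, n_perm = 200, seed = 1,
                            tol = 1e-6, n_lambda = 100)
  expect_equal(unname(pp$p[d$planted]), 1 / 201)
})

test_that("bh_adjust matches the independent implementation", {
  p <- c(0.01, 0.02, 0.03, 0.5)
  expect_equal(bh_adjust(p), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.2), 0.2)
  withr::local_seed(4)
  for (k in 1:20) {
    pv <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(pv), stats::p.adjust(pv, method = "BH"))
  }
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("run_hisig composes the stages reproducibly", {
  d <- simulate_dataset(synthetic_spec(n_genes = 60, branching = c(6, 2),
                                       planted_systems = 2, effect_size = 4,
                                       seed = 5))
  res <- run_hisig(d$tracks$zscores, d$hierarchy, n_lambda = 100,
                   n_perm = 100, seed = 3, tol = 1e-6)
  expect_s3_class(res, "hisig_result")
  expect_identical(res, run_hisig(d$tracks$zscores, d$hierarchy,
                                  n_lambda = 100, n_perm = 100, seed = 3,
                                  tol = 1e-6))
  expect_true(all(res$q >= res$p - 1e-12))
  expect_identical(res$significant, res$q < 0.25)

  # shrinking the cutoff can only shrink the significant set
  res05 <- run_hisig(d$tracks$zscores, d$hierarchy, n_lambda = 100,
                     n_perm = 100, seed = 3, fdr_cutoff = 0.05, tol = 1e-6)
  expect_true(all(res05$system_id[res05$significant] %in%
                    res$system_id[res$significant]))

  # signed track with abs transform: design sees nonnegative values
  expect_true(all(hiersys:::apply_transform(d$tracks$zscores) >= 0))

  # round trip through the TSV writer
  f <- withr::local_tempfile(fileext = ".tsv")
  write_hisig_result(res, f)
  back <- read_hisig_result(f)
  expect_equal(back$system_id, res$system_id)
  expect_equal(back$q, res$q, tolerance = 1e-10)
})

test_that("hotspot intersection is plain set intersection with q attached", {
  mk <- function(sig, track) {
    structure(data.frame(system_id = c("s1", "s2", "s3", "s4"),
                         n_genes = 2, S = 0.5, p = 0.01,
                         q = c(0.01, 0.02, 0.03, 0.9),
                         significant = c("s1", "s2", "s3", "s4") %in% sig),
              class = c("hisig_result", "data.frame"), track = track)
  }
  a <- mk(c("s1", "s2", "s3"), "mut")
  b <- mk(c("s2", "s3", "s4"), "surv")
  got <- intersect_hotspots(a, b)
  expect_equal(got$system_id, c("s2", "s3"))
  expect_equal(names(got), c("system_id", "q_mut", "q_surv"))
  expect_equal(intersect_hotspots(a, a)$system_id, c("s1", "s2", "s3"))

  cc <- mk(c("s3", "s4"), "dep")
  expect_equal(intersect_hotspots(a, b, cc)$system_id, "s3")

  bad <- mk("s1", "x"); bad$system_id[4] <- "zz"
  expect_error(intersect_hotspots(a, bad), "different hierarchies")
  expect_error(intersect_hotspots(a), "at least two")
})
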