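test_that("preprocess removes constant genes and log-transforms counts", {
  m <- matrix(c(1, 1, 0, 3, 5, 2,
                1, 1, 0, 7, 2, 9), 6, 2,
              dimnames = list(paste0("g", 1:6), c("s1", "s2")))
  expr <- toy_expr(m, space = "log2")
  pre <- preprocess(expr)
  # manual filter: g1, g2, g3 are constant across samples
  expect_equal(pre$gene_ids, c("g4", "g5", "g6"))
  expect_equal(attr(pre, "removed_genes"), c("g1", "g2", "g3"))

  cnt <- toy_expr(matrix(c(3, 0, 1, 7), 2, 2), space = "counts")
  prec <- preprocess(cnt)
  expect_equal(prec$values[1, 1], log2(4))   # pseudocount of 1
  expect_equal(preprocess(prec)$values, prec$values)   # idempotent

  expect_error(preprocess(toy_expr(matrix(1, 3, 4))), "all genes removed")
})

test_that("rank-1 noiseless data is reconstructed exactly", {
  set.seed(3)
  a <- abs(rnorm(30)) + 0.1
  p <- abs(rnorm(12)) + 0.1
  X <- a %*% t(p)
  expr <- toy_expr(X)
  fit <- factorize_single(expr, 1, seed = 1)
  rel <- norm(X - fit$A %*% fit$P, "F") / norm(X, "F")
  expect_lt(rel, 1e-6)
})

test_that("rank-1 fit is at least as good as the clipped-SVD baseline", {
  set.seed(4)
  X <- matrix(abs(rnorm(40 * 15)), 40, 15)
  expr <- toy_expr(X)
  fit <- factorize_single(expr, 1, seed = 2, tol = 1e-14,
                          n_iterations = 10000)
  obj_fit <- sum((X - fit$A %*% fit$P)^2)
  sv <- svd(X, nu = 1, nv = 1)
  u <- pmax(sv$u[, 1] * sign(sum(sv$u[, 1])), 0)
  v <- pmax(sv$v[, 1] * sign(sum(sv$v[, 1])), 0)
  obj_svd <- sum((X - sv$d[1] * u %*% t(v))^2)
  expect_lte(obj_fit, obj_svd + 1e-8)
  expect_true(all(fit$P >= 0))
})

test_that("objective trace is monotone non-increasing and bounds are enforced", {
  truth <- fixture_truth(1)
  expr <- simulate_expression(truth)
  pre <- preprocess(expr)
  fit <- factorize_single(pre, 3, seed = 5, n_iterations = 50)
  expect_true(all(diff(fit$objective_trace) <= 1e-8))
  fits <- factorize_single(pre, 3, seed = 5, n_iterations = 50,
                           sparsity_penalty = 0.6)
  expect_true(all(diff(fits$objective_trace) <= 1e-8))
  expect_error(factorize_single(pre, 1000, seed = 1), "n_patterns")
})

test_that("amplitude columns are scaled to unit maximum with scale folded into P", {
  fit <- fixture_fit(1)
  expect_equal(unname(apply(fit$A, 2, max)), rep(1, fit$K_final))
})

test_that("consensus recovers planted patterns and collapses over-requested K", {
  truth <- fixture_truth(1)
  fit <- fixture_fit(1)
  expect_equal(fit$K_final, 4L)
  mp <- match_patterns(fit$A, truth$A_true)
  expect_true(all(mp$cosines >= 0.9))
  expect_true(all(sort(mp$match) == 1:4))   # distinct patterns matched

  pre <- preprocess(simulate_expression(truth))
  fit8 <- consensus_factorize(pre, 8, n_sets = 3, sparsity_penalty = 0.6,
                              seed = 31)
  expect_lte(fit8$K_final, 8L)
  co <- abs(cor(fit8$A[rownames(truth$A_true), ], truth$A_true))
  expect_true(all(apply(co, 2, max) >= 0.85))
})

test_that("consensus of identical duplicated subsets equals the single-subset fit", {
  truth <- fixture_truth(1)
  expr <- simulate_expression(truth)
  sub <- subset_expression(expr, samples = expr$sample_ids[1:60])
  dup_vals <- cbind(sub$values, sub$values)
  colnames(dup_vals) <- c(paste0("a_", sub$sample_ids), paste0("b_", sub$sample_ids))
  dup <- toy_expr(dup_vals, genes = sub$gene_ids,
                  samples = colnames(dup_vals))
  dup <- preprocess(dup)
  subsets <- stats::setNames(rep(1:2, each = 60), dup$sample_ids)
  cons <- consensus_factorize(dup, 3, n_sets = 2, seed = 9,
                              subsets = subsets, n_iterations = 500)
  single <- factorize_single(subset_expression(dup, samples = dup$sample_ids[1:60]),
                             3, seed = 9 + 1, n_iterations = 500)
  co <- abs(cor(cons$A, single$A))
  expect_true(all(apply(co, 1, max) > 0.99))   # same patterns up to order
})

test_that("permuting input sample order permutes P identically and leaves A unchanged", {
  truth <- fixture_truth(1)
  expr <- simulate_expression(truth)
  pre <- preprocess(expr)
  perm <- sample(seq_along(pre$sample_ids))
  pre_perm <- subset_expression(pre, samples = pre$sample_ids[perm])
  f1 <- consensus_factorize(pre, 4, n_sets = 3, seed = 11, n_iterations = 300)
  f2 <- consensus_factorize(pre_perm, 4, n_sets = 3, seed = 11, n_iterations = 300)
  expect_equal(f1$A, f2$A)
  expect_equal(f1$P[, pre_perm$sample_ids], f2$P)
})

test_that("cells are annotated by maximal marker expression with tie and zero handling", {
  m <- matrix(c(5, 0, 0,
                0, 4, 0,
                2, 2, 0,
                0, 0, 0), nrow = 3,
              dimnames = list(c("Ncr1", "Cd3e", "Itgam"),
                              c("nk", "t", "tie", "none")))
  expr <- toy_expr(m, genes = rownames(m), samples = colnames(m))
  markers <- list(NK = "Ncr1", T_cell = "Cd3e")
  ann <- annotate_cell_types(expr, markers)
  expect_equal(ann$cell_type, c("NK", "T_cell", "NK", "unassigned"))
  expect_equal(ann$tie, c(FALSE, FALSE, TRUE, FALSE))
  expect_error(annotate_cell_types(expr, list()), "empty")
  expect_error(annotate_cell_types(expr, list(B = "Ms4a1")), "no marker genes")
})

test_that("marker-based annotation recovers planted cell types at high accuracy", {
  truth <- fixture_truth(1)
  expr <- simulate_expression(truth)
  # identity-pattern top loadings as canonical markers
  sets <- truth_program_sets(truth, top_fraction = 0.05)
  types <- unique(unname(truth$cell_type_labels))
  markers <- stats::setNames(unclass(sets)[seq_along(types)], types)
  ann <- annotate_cell_types(expr, markers)
  acc <- mean(ann$cell_type == unname(truth$cell_type_labels))
  expect_gte(acc, 0.95)
})
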