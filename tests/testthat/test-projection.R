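test_that("feature alignment retains mapped genes in source order, invariant to target order", {
  truth <- fixture_truth(1)
  tg <- simulate_target_species(truth, homolog_dropout = 0.3)
  al <- align_features(truth$A_true, tg$expr, tg$homolog_map)
  expect_equal(al$genes_used, 140)
  expect_equal(al$genes_dropped, 60)
  expect_equal(nrow(al$A_sub), nrow(al$Y_sub))
  expect_equal(toupper(rownames(al$A_sub)), rownames(al$Y_sub))

  # identity map, same universe
  src_expr <- simulate_expression(truth)
  al_id <- align_features(truth$A_true, src_expr)
  expect_equal(al_id$genes_used, 200)

  # shuffling the target gene order changes nothing
  shuf <- sample(seq_len(200))
  expr_shuf <- expression_matrix(tg$expr$values[shuf, ],
                                 gene_ids = tg$expr$gene_ids[shuf],
                                 sample_ids = tg$expr$sample_ids,
                                 space = "log2")
  al2 <- align_features(truth$A_true, expr_shuf, tg$homolog_map)
  expect_identical(al$A_sub, al2$A_sub)
  expect_identical(al$Y_sub, al2$Y_sub)
})

test_that("noiseless projection recovers pattern weights exactly", {
  truth <- fixture_truth(1)
  set.seed(21)
  P0 <- matrix(runif(4 * 25), 4, 25,
               dimnames = list(colnames(truth$A_true), sprintf("s%02d", 1:25)))
  Y <- expression_matrix(truth$A_true %*% P0, space = "log2")
  pr <- project(truth$A_true, Y, mode = "ols", center_genes = FALSE)
  expect_lt(norm(pr$P_new - P0, "F") / norm(P0, "F"), 1e-8)

  # basis case: a sample equal to pattern 2's amplitude column
  y2 <- expression_matrix(truth$A_true[, 2, drop = FALSE],
                          sample_ids = "b", space = "log2")
  pr2 <- project(truth$A_true, y2)
  expect_equal(unname(pr2$P_new[, 1]), c(0, 1, 0, 0), tolerance = 1e-10)
})

test_that("ols projection without centering is linear in the data", {
  truth <- fixture_truth(1)
  set.seed(22)
  Y1 <- matrix(abs(rnorm(200 * 5)), 200, 5)
  Y2 <- matrix(abs(rnorm(200 * 5)), 200, 5)
  gi <- rownames(truth$A_true); si <- sprintf("s%d", 1:5)
  p1 <- project(truth$A_true, toy_expr(Y1, gi, si))$P_new
  p2 <- project(truth$A_true, toy_expr(Y2, gi, si))$P_new
  p12 <- project(truth$A_true, toy_expr(2 * Y1 + 3 * Y2, gi, si))$P_new
  expect_equal(p12, 2 * p1 + 3 * p2, tolerance = 1e-8)
})

test_that("degenerate projections are flagged or rejected", {
  truth <- fixture_truth(1)
  A2 <- truth$A_true
  A2[, 2] <- A2[, 1]                     # collinear patterns
  Y <- simulate_expression(truth)
  expect_error(project(A2, Y), "collinear|rank")

  # a panel with no genes loading on one pattern
  A3 <- truth$A_true
  only3 <- which(A3[, 3] > 0 & rowSums(A3[, -3]) == 0)
  panel_genes <- setdiff(rownames(A3), rownames(A3)[A3[, 3] > 0])[1:30]
  Yp <- subset_expression(Y, genes = panel_genes)
  expect_warning(prp <- project_panel(A3, Yp), "unidentifiable")
  expect_true("pattern_3" %in% prp$unidentifiable)
  expect_true(all(is.na(prp$P_new["pattern_3", ])))

  # duplicated sample gives identical projected columns
  Yd <- toy_expr(cbind(Y$values[, 1], Y$values[, 1]), rownames(truth$A_true),
                 c("d1", "d2"))
  prd <- project(truth$A_true, Yd)
  expect_equal(prd$P_new[, 1], prd$P_new[, 2], ignore_attr = TRUE)
})

test_that("nnls projection returns non-negative weights close to ols on clean data", {
  truth <- fixture_truth(1)
  set.seed(23)
  P0 <- matrix(runif(4 * 10) + 0.2, 4, 10,
               dimnames = list(colnames(truth$A_true), sprintf("s%d", 1:10)))
  Y <- expression_matrix(truth$A_true %*% P0, space = "log2")
  prn <- project(truth$A_true, Y, mode = "nnls")
  expect_true(all(prn$P_new >= 0))
  expect_equal(prn$P_new, P0, tolerance = 1e-6)
})

test_that("cross-species projection with homolog dropout recovers planted weights", {
  truth <- fixture_truth(1)
  fit <- fixture_fit(1)
  mp <- match_patterns(fit$A, truth$A_true)
  tg <- simulate_target_species(truth, homolog_dropout = 0.3)
  pr <- project(fit$A, tg$expr, homologs = tg$homolog_map)
  cors <- sapply(seq_len(4), function(k) {
    cor(pr$P_new[k, ], tg$P_true[mp$match[k], ])
  })
  expect_true(all(cors >= 0.9))
})

test_that("planted treatment difference transfers to the projected target species", {
  truth <- fixture_truth(1)
  fit <- fixture_fit(1)
  mp <- match_patterns(fit$A, truth$A_true)
  kk <- which(mp$match == truth$k_star)
  tg <- simulate_target_species(truth, n_cells = 900, homolog_dropout = 0.3)
  pr <- project(fit$A, tg$expr, homologs = tg$homolog_map)
  pw <- tidy(pr)
  nk <- pw[pw$pattern == rownames(pr$P_new)[kk] & pw$cell_type == "NK", ]
  expect_gte(min(table(nk$treatment)), 150)
  cmp <- compare_groups(nk, weight, treatment)
  expect_lt(cmp$p_adj, 0.01)
  # same sign as planted: treated mean higher
  treated_is_1 <- cmp$group1 == "anti-CTLA-4"
  expect_true(ifelse(treated_is_1, cmp$mean1 > cmp$mean2, cmp$mean2 > cmp$mean1))
})

test_that("pseudo-bulk projection tracks per-sample mean planted weights", {
  truth <- fixture_truth(1)
  fit <- fixture_fit(1)
  mp <- match_patterns(fit$A, truth$A_true)
  kk <- which(mp$match == truth$k_star)
  tg <- simulate_target_species(truth, n_cells = 600, homolog_dropout = 0)
  # average cells into 30 pseudo-samples of 20 cells
  grp <- rep(seq_len(30), each = 20)
  bulk_vals <- sapply(split(seq_len(600), grp), function(ix) {
    rowMeans(tg$expr$values[, ix, drop = FALSE])
  })
  rownames(bulk_vals) <- tg$expr$gene_ids
  bulk <- toy_expr(bulk_vals, genes = tg$expr$gene_ids,
                   samples = paste0("pb", seq_len(30)))
  prb <- project_bulk(fit$A, bulk, homologs = tg$homolog_map)
  mean_w <- tapply(tg$P_true[truth$k_star, ], grp, mean)
  expect_gte(cor(prb$P_new[kk, ], mean_w, method = "spearman"), 0.9)
})
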