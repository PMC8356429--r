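test_that("pattern markers assign basis-like rows exactly and flag ties", {
  A <- rbind(g1 = c(0, 5, 0), g2 = c(1, 1, 1), g3 = c(2, 0, 0))
  colnames(A) <- paste0("pattern_", 1:3)
  mk <- pattern_markers(A)
  r1 <- mk[mk$gene_id == "g1", ]
  expect_equal(r1$pattern, "pattern_2")
  expect_equal(r1$distance, 0)
  expect_equal(r1$rank, 1L)
  r2 <- mk[mk$gene_id == "g2", ]
  expect_equal(r2$pattern, "pattern_1")   # lowest index on tie
  expect_true(r2$tie)
})

test_that("pattern marker assignments equal brute-force enumeration on random A", {
  set.seed(11)
  A <- matrix(abs(rnorm(90)), 30, 3,
              dimnames = list(sprintf("g%02d", 1:30), paste0("pattern_", 1:3)))
  mk <- pattern_markers(A)
  # independent brute force: scale rows, enumerate all distances
  S <- A / apply(A, 1, max)
  for (g in rownames(A)) {
    d <- sapply(1:3, function(k) {
      e <- c(0, 0, 0); e[k] <- 1
      sqrt(sum((S[g, ] - e)^2))
    })
    expect_equal(mk$pattern[mk$gene_id == g],
                 paste0("pattern_", which.min(d)))
    expect_equal(mk$distance[mk$gene_id == g], min(d))
  }
  # ranks are 1..n within each pattern with no gaps
  for (p in unique(mk$pattern)) {
    expect_equal(sort(mk$rank[mk$pattern == p]), seq_len(sum(mk$pattern == p)))
  }
})

test_that("pattern markers are invariant to positive row rescaling and handle degeneracies", {
  set.seed(12)
  A <- matrix(abs(rnorm(60)), 20, 3,
              dimnames = list(sprintf("g%02d", 1:20), paste0("pattern_", 1:3)))
  scaled <- A * runif(20, 0.5, 10)
  expect_equal(pattern_markers(A)$pattern, pattern_markers(scaled)$pattern)

  A2 <- A; A2[3, ] <- 0
  mk <- pattern_markers(A2)
  expect_false("g03" %in% mk$gene_id)
  expect_equal(attr(mk, "excluded_genes"), "g03")

  A3 <- A; A3[, 2] <- 0
  expect_warning(mk3 <- pattern_markers(A3), "degenerate")
  expect_false("pattern_2" %in% mk3$pattern)
})

test_that("exact enrichment p equals exhaustive enumeration on a 5-gene universe", {
  A <- matrix(c(1, 0.8, 0.1, 0.05, 0,
                0, 0.2, 0.9, 1, 0.7), 5, 2,
              dimnames = list(paste0("g", 1:5), c("pattern_1", "pattern_2")))
  sets <- geneset_collection(list(top = c("g1", "g2")))
  enr <- geneset_enrichment(A, sets, exact_if_feasible = TRUE, seed = 1)
  expect_equal(unique(enr$method), "exact")
  # independent hand enumeration over all C(5,2) = 10 subsets
  S <- sweep(A, 2, apply(A, 2, max), "/")
  pairs <- combn(5, 2)
  for (k in 1:2) {
    null <- apply(pairs, 2, function(ix) mean(S[ix, k]))
    obs <- mean(S[c(1, 2), k])
    expect_equal(enr$p[enr$pattern == paste0("pattern_", k)],
                 mean(null >= obs))
  }
})

test_that("saturated sets, no-overlap sets and the FDR family are handled", {
  set.seed(13)
  A <- matrix(abs(rnorm(40)), 20, 2,
              dimnames = list(sprintf("g%02d", 1:20), c("pattern_1", "pattern_2")))
  sets <- geneset_collection(list(all = rownames(A), missing = c("zz1", "zz2")))
  enr <- geneset_enrichment(A, sets, n_perm = 200, seed = 2,
                            exact_if_feasible = FALSE)
  expect_true(all(enr$p[enr$gene_set == "all"] == 1))
  expect_true(all(is.na(enr$p[enr$gene_set == "missing"])))
  expect_true(all(is.na(enr$p_adj[enr$gene_set == "missing"])))
  ok <- !is.na(enr$p)
  expect_true(all(enr$p_adj[ok] >= enr$p[ok]))
})

test_that("sampled enrichment p converges to the exact p", {
  set.seed(14)
  A <- matrix(abs(rnorm(36)), 18, 2,
              dimnames = list(sprintf("g%02d", 1:18), c("pattern_1", "pattern_2")))
  sets <- geneset_collection(list(s = c("g01", "g02", "g03")))
  exact <- geneset_enrichment(A, sets, exact_if_feasible = TRUE)
  err <- sapply(c(1e3, 1e4), function(np) {
    samp <- geneset_enrichment(A, sets, n_perm = np, seed = 3,
                               exact_if_feasible = FALSE)
    max(abs(samp$p - exact$p))
  })
  expect_lt(err[2], 0.02)
  expect_lte(err[2], err[1] + 0.01)
})

test_that("the planted activation program is the top-enriched set for its pattern", {
  truth <- fixture_truth(1)
  fit <- fixture_fit(1)
  mp <- match_patterns(fit$A, truth$A_true)
  kk <- which(mp$match == truth$k_star)
  sets <- truth_program_sets(truth)
  enr <- geneset_enrichment(fit$A, sets, n_perm = 1000, seed = 4)
  sub <- enr[enr$pattern == colnames(fit$A)[kk], ]
  expect_equal(sub$gene_set[which.max(sub$z)], paste0("program_", truth$k_star))
  expect_lt(sub$p_adj[sub$gene_set == paste0("program_", truth$k_star)], 0.05)
})

test_that("BH adjustment matches the hand step-up computation and its properties", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(15)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  # hand step-up on a printed fixture
  p2 <- c(0.005, 0.009, 0.05, 0.5, 0.9)
  expect_equal(bh_adjust(p2), c(0.0225, 0.0225, 1/12, 0.625, 0.9))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})
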