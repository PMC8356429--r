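test_that("cell gating follows the required/excluded transcript rule", {
  m <- rbind(NCR1  = c(2,   2, 0, 2, 2, 1),
             NKG7  = c(1,   1, 1, 0, 1, 1),
             FCGR3A= c(0.5, 1, 1, 1, 1, 1),
             CD3D  = c(0, 0.1, 0, 0, 0, 0),
             CD4   = c(0,   0, 0, 0, 2, 0))
  expr <- toy_expr(m, genes = rownames(m), samples = paste0("c", 1:6))
  gate <- gate_cells(expr, required_genes = c("NCR1", "NKG7", "FCGR3A"),
                     excluded_genes = c("CD3D", "CD4"))
  # hand-derived: c1 passes; c2 fails CD3D>0; c3 fails NCR1=0; c4 fails NKG7=0;
  # c5 fails CD4>0; c6 passes
  expect_equal(gate$pass, c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE))

  expect_error(gate_cells(expr, character()), "non-empty")
  expect_error(gate_cells(expr, c("NCR1", "GZMB")), "GZMB")
})

test_that("group comparisons match exact rank-sum enumeration and handle nulls", {
  df <- tibble::tibble(w = c(1, 2, 3, 11, 12, 13),
                       g = rep(c("a", "b"), each = 3))
  cmp <- compare_groups(df, w, g)
  expect_equal(cmp$p, 0.1)   # exact two-sided, complete separation at n=3/3

  same <- tibble::tibble(w = rep(c(1, 2, 3, 4), 2),
                         g = rep(c("a", "b"), each = 4))
  expect_gt(compare_groups(same, w, g)$p, 0.99)

  const <- tibble::tibble(w = rep(5, 6), g = rep(c("a", "b"), each = 3))
  cc <- compare_groups(const, w, g)
  expect_equal(cc$p, 1)
  expect_true(cc$degenerate)

  expect_error(compare_groups(df[1:3, ], w, g), "2 groups")
})

test_that("exact rank-sum p-values equal full enumeration for small groups", {
  # independent oracle: enumerate all assignments of ranks to group 1
  exact_ranksum_p <- function(x, y) {
    n1 <- length(x); n <- n1 + length(y)
    r <- rank(c(x, y))
    w_obs <- sum(r[seq_len(n1)])
    combos <- combn(n, n1)
    w_all <- apply(combos, 2, function(ix) sum(r[ix]))
    # two-sided: double the smaller tail (as the exact test defines it)
    mu <- n1 * (n + 1) / 2
    min(1, 2 * min(mean(w_all >= w_obs), mean(w_all <= w_obs)))
  }
  set.seed(31)
  for (i in 1:5) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    x <- round(rnorm(n1), 2); y <- round(rnorm(n2, 0.5), 2)
    if (anyDuplicated(c(x, y))) next   # oracle written for tie-free data
    df <- tibble::tibble(w = c(x, y), g = rep(c("a", "b"), c(n1, n2)))
    expect_equal(compare_groups(df, w, g)$p, exact_ranksum_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("star coding follows the 0.05/0.01/0.001 convention on adjusted p", {
  df <- tibble::tibble(
    w = c(rnorm(20), rnorm(20, 10)),
    g = rep(c("a", "b"), each = 20)
  )
  cmp <- compare_groups(df, w, g)
  expect_equal(cmp$stars, "***")
  same <- tibble::tibble(w = rep(c(1, 2, 3, 4), 2),
                         g = rep(c("a", "b"), each = 4))
  expect_equal(compare_groups(same, w, g)$stars, "ns")
})

test_that("AUC equals the pairwise-count oracle, with half credit for ties", {
  df <- tibble::tibble(w = c(0.9, 0.8, 0.1, 0.2),
                       r = c("responder", "responder", "non-responder", "non-responder"))
  expect_equal(roc_auc(df, w, r)$auc, 1)

  set.seed(32)
  for (i in 1:3) {
    w <- sample(seq(0, 1, 0.1), 20, replace = TRUE)   # forces ties
    lab <- sample(c("responder", "non-responder"), 20, replace = TRUE,
                  prob = c(0.4, 0.6))
    if (length(unique(lab)) < 2) next
    df <- tibble::tibble(w = w, r = lab)
    pos <- w[lab == "responder"]; neg <- w[lab == "non-responder"]
    oracle <- mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
    expect_equal(roc_auc(df, w, r)$auc, oracle, tolerance = 1e-12)
    # independent implementation agrees
    proc_auc <- as.numeric(pROC::auc(pROC::roc(
      response = lab, predictor = w, levels = c("non-responder", "responder"),
      direction = "<", quiet = TRUE)))
    expect_equal(roc_auc(df, w, r)$auc, proc_auc, tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone transforms and detects the null", {
  set.seed(33)
  df <- tibble::tibble(w = rnorm(2000),
                       r = sample(c("responder", "non-responder"), 2000,
                                  replace = TRUE))
  r1 <- roc_auc(df, w, r)
  expect_lt(abs(r1$auc - 0.5), 0.03)
  df$w2 <- exp(3 * df$w) - 5
  expect_equal(roc_auc(df, w2, r)$auc, r1$auc)
  expect_error(roc_auc(df[df$r == "responder", ], w, r), "both")
})

test_that("the Cox fit maximizes the Breslow partial likelihood (toy oracle)", {
  toy <- clinical_table(tibble::tibble(
    sample_id = paste0("s", 1:6),
    os_time = c(2, 5, 7, 11, 13, 17),
    os_event = c(1, 1, 0, 1, 1, 1),
    age = c(50, 60, 55, 65, 45, 70),
    x = c(0.2, 1.5, 0.8, 2.1, 0.1, 1.0)
  ))
  fit <- cox_fit(toy, "x")
  # independent oracle: maximize the hand-written partial log-likelihood
  pll <- function(b) {
    ll <- 0
    for (i in which(toy$os_event == 1)) {
      risk <- toy$os_time >= toy$os_time[i]
      ll <- ll + b * toy$x[i] - log(sum(exp(b * toy$x[risk])))
    }
    ll
  }
  b_grid <- optimize(pll, c(-5, 5), maximum = TRUE, tol = 1e-10)$maximum
  expect_equal(tidy(fit)$coef, b_grid, tolerance = 1e-4)
  expect_equal(tidy(fit)$hr, exp(tidy(fit)$coef))
  expect_true(attr(fit, "converged"))
})

test_that("Cox guards reject unusable designs", {
  toy <- clinical_table(tibble::tibble(
    sample_id = paste0("s", 1:4), os_time = 1:4, os_event = c(1, 0, 0, 0),
    age = c(50, 60, 55, 65), x = 1:4
  ))
  expect_error(cox_fit(toy, "x"), "2 events")
  toy$os_event <- c(1, 1, 1, 0)
  toy$x <- rep(2, 4)
  expect_error(cox_fit(toy, "x"), "constant")
})

test_that("correlations match the rank formula and reject degenerate input", {
  x <- 1:10
  expect_equal(correlate(x, x^3)$rho, 1)
  expect_equal(correlate(x, -x)$rho, -1)
  set.seed(34)
  y <- rnorm(10)
  # hand rank formula (no ties): rho = 1 - 6 sum d^2 / (n (n^2 - 1))
  d <- rank(x) - rank(y)
  expect_equal(correlate(x, y)$rho, 1 - 6 * sum(d^2) / (10 * 99))
  expect_equal(correlate(x, y, method = "pearson")$rho, cor(x, y))
  expect_error(correlate(x, rep(1, 10)), "constant")
  expect_error(correlate(1:2, 2:3), "at least 3")
})

test_that("score-table correlation shares samples, adjusts and stars", {
  set.seed(35)
  gv <- setNames(rnorm(30, 5, 1), paste0("s", 1:30))
  scores <- tibble::tibble(sample_id = paste0("s", 1:30),
                           NK_active = unname(gv),
                           Noise = rnorm(30))
  res <- correlate_scores(scores, gv)
  expect_equal(res$rho[res$cell_type == "NK_active"], 1)
  expect_true(all(res$p_adj >= res$p))
  bad <- tibble::tibble(sample_id = paste0("t", 1:5), s = rnorm(5))
  expect_error(correlate_scores(bad, gv), "no shared samples")
})

test_that("gene expression positively linked to a planted score is recovered", {
  truth <- fixture_truth(1)
  cl <- simulate_clinical(truth, n_patients = 200)
  bulk <- simulate_patient_bulk(truth, cl)
  # pick a gene loading strongly on the activation program
  g <- rownames(truth$A_true)[which.max(truth$A_true[, truth$k_star])]
  scores <- tibble::tibble(sample_id = cl$sample_id,
                           NK_activated = cl$activation_weight)
  res <- correlate_scores(scores, gene_values(bulk, g))
  expect_gt(res$rho[res$cell_type == "NK_activated"], 0.5)
  expect_lt(res$p_adj[res$cell_type == "NK_activated"], 0.001)
})
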