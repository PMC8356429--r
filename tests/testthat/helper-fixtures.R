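# Shared fixtures. Factorizations are memoized per seed so the suite does
# not refit the same synthetic dataset in every file.

.shared <- new.env(parent = emptyenv())

fixture_truth <- function(seed = 1, ...) {
  key <- paste0("truth_", seed, "_", paste(c(...), collapse = "_"))
  if (is.null(.shared[[key]])) .shared[[key]] <- simulate_truth(seed = seed, ...)
  .shared[[key]]
}

fixture_fit <- function(seed = 1) {
  key <- paste0("fit_", seed)
  if (is.null(.shared[[key]])) {
    truth <- fixture_truth(seed)
    pre <- preprocess(simulate_expression(truth))
    .shared[[key]] <- consensus_factorize(pre, 4, n_sets = 3,
                                          sparsity_penalty = 0.6,
                                          seed = seed + 20)
  }
  .shared[[key]]
}

# Hungarian matching of fitted amplitude columns to true columns; returns
# per-pattern cosine and the matching (true column index per fitted column)
match_patterns <- function(A_est, A_true) {
  co <- abs(stats::cor(A_est[rownames(A_true), , drop = FALSE], A_true))
  m <- as.integer(clue::solve_LSAP(co, maximum = TRUE))
  cosines <- vapply(seq_along(m), function(k) {
    a <- A_est[rownames(A_true), k]
    b <- A_true[, m[k]]
    sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }, numeric(1))
  list(match = m, cosines = cosines)
}

# small dense expression fixture with deterministic values
toy_expr <- function(values, genes = NULL, samples = NULL, space = "log2") {
  genes <- genes %||% rownames(values) %||% sprintf("g%d", seq_len(nrow(values)))
  samples <- samples %||% colnames(values) %||% sprintf("s%d", seq_len(ncol(values)))
  expression_matrix(values, gene_ids = genes, sample_ids = samples,
                    space = space)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# cells ordered along a 1-D activation gradient of the planted program:
# NK identity usage constant, activation usage increasing linearly
gradient_fixture <- function(truth, n_cells = 120, noise_sd = truth$noise_sd,
                             seed = 7) {
  set.seed(seed)
  K <- ncol(truth$A_true)
  ids <- sprintf("gcell_%03d", seq_len(n_cells))
  P <- matrix(0, K, n_cells, dimnames = list(colnames(truth$A_true), ids))
  P[1, ] <- 1                                        # NK identity
  grad <- seq(0, 2, length.out = n_cells)
  P[truth$k_star, ] <- grad
  X <- pmax(truth$A_true %*% P + rnorm(nrow(truth$A_true) * n_cells, 0, noise_sd), 0)
  expr <- expression_matrix(X, gene_ids = rownames(truth$A_true),
                            sample_ids = ids, space = "log2")
  list(expr = expr, weights = stats::setNames(grad, ids), P = P)
}
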