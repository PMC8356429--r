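#' Preprocess an expression matrix for factorization
#'
#' Removes genes with zero standard deviation and, for count-space input,
#' applies the `log2(x + 1)` transform. Idempotent on already-log2 data.
#' The removed-gene list is kept in the `removed_genes` attribute.
#'
#' @param expr An [expression_matrix()] in counts or log2 space.
#' @return A log2-space [expression_matrix()] of the remaining genes.
#' @export
preprocess <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  v <- expr$values
  if (expr$space == "counts") v <- log2(v + 1)
  sds <- apply(v, 1, stats::sd)
  keep <- sds > 0
  if (!any(keep)) stop("all genes removed (zero standard deviation)", call. = FALSE)
  out <- expression_matrix(v[keep, , drop = FALSE],
                           gene_ids = expr$gene_ids[keep],
                           sample_ids = expr$sample_ids,
                           sample_meta = expr$sample_meta, space = "log2")
  attr(out, "removed_genes") <- expr$gene_ids[!keep]
  out
}

# One HALS sweep updating the columns of A (X ~ A P). Amplitudes live in
# the unit box [0, 1] (the package's scale convention: gene weights are
# relative to the pattern's strongest gene), which pins the coefficient
# scale so the L1 threshold on P is meaningful; each column subproblem is
# an exact separable box-constrained solve, so the objective cannot
# increase.
hals_update_A <- function(X, A, P, lambda, mask = NULL) {
  G <- X %*% t(P)            # genes x K
  H <- P %*% t(P)            # K x K
  for (k in seq_len(ncol(A))) {
    hkk <- H[k, k]
    if (hkk < 1e-12) next
    ak <- pmin(pmax((G[, k] - A %*% H[, k] + A[, k] * hkk) / hkk, 0), 1)
    if (!is.null(mask)) ak <- ak * mask[, k]
    A[, k] <- ak
  }
  A
}

# exact soft-thresholded column updates of P (L1 penalty lambda); an
# optional support mask freezes structural zeros (debias phase)
hals_update_P <- function(X, A, P, lambda, mask = NULL) {
  G <- crossprod(A, X)       # K x samples
  H <- crossprod(A)          # K x K
  for (k in seq_len(nrow(P))) {
    hkk <- H[k, k]
    if (hkk < 1e-12) next
    pk <- pmax((G[k, ] - H[k, ] %*% P + hkk * P[k, ] - lambda / 2) / hkk, 0)
    if (!is.null(mask)) pk <- pk * mask[k, ]
    P[k, ] <- pk
  }
  P
}

nmf_objective <- function(X, A, P, lambda) {
  sum((X - A %*% P)^2) + lambda * sum(P)
}

# scale each A column to unit maximum, folding the inverse scale into P;
# makes pattern weights comparable across patterns
normalize_factors <- function(A, P) {
  s <- apply(A, 2, max)
  s[s <= 0] <- 1
  list(A = sweep(A, 2, s, "/"), P = sweep(P, 1, s, "*"))
}

#' Factorize an expression matrix into K non-negative patterns
#'
#' Minimizes `||X - A P||_F^2 + lambda ||P||_1` with `0 <= A <= 1`
#' (amplitudes constrained to the unit box — the package's scale
#' convention that gene weights are relative to a pattern's strongest
#' gene) and `P >= 0`, by alternating exact column-wise (HALS) updates.
#' Fixing the amplitude scale is what makes the sparsity penalty on the
#' pattern weights well posed: with a free scale, an L1 penalty on both
#' factors can always be partly evaded by rescaling.
#'
#' The fit starts from a seeded random non-negative initialization. With
#' `sparsity_penalty = 0` the alternating updates simply run to
#' convergence. With `sparsity_penalty > 0` the solver uses
#' screen-and-refit estimation, standard in sparse dictionary learning:
#' (1) the unpenalized fit is obtained first (warm phase); (2) one exact
#' penalized pattern-matrix sweep at the unit-max amplitude scale
#' soft-thresholds the pattern weights, selecting the support (structural
#' zeros); (3) the factors are refit unpenalized on that support, removing
#' the L1 shrinkage bias. The recorded `objective_trace` is the trace of
#' the final (support-constrained) refit and is non-increasing; iteration
#' stops early when the relative decrease falls below `tol`. After
#' fitting, each amplitude column is scaled to unit maximum with the
#' inverse scale folded into the pattern matrix.
#'
#' @param expr A preprocessed log2-space [expression_matrix()].
#' @param n_patterns Number of patterns K (>= 1, at most `min(dim)`).
#' @param n_iterations Maximum alternating sweeps (default 2000, a
#'   desk-scale setting; convergence usually stops far earlier).
#' @param sparsity_penalty L1 penalty `lambda` (>= 0); 0 disables sparsity.
#' @param seed Seed for the random initialization.
#' @param tol Relative objective-decrease tolerance for early stopping.
#' @param n_restarts Number of seeded random restarts; the fit with the
#'   lowest final penalized objective is returned. Restarts guard against
#'   poor local optima (including pattern collapse under strong sparsity).
#' @param amplitude_cut In sparse mode, gene weights below this fraction
#'   of their pattern's strongest gene weight are screened out before the
#'   refit (default 0.1). Amplitude sparsity restores identifiability:
#'   dense mixtures of sparse programs can otherwise fit equally well.
#' @return An object of class `factorization_result`: `A` (genes x K,
#'   columns `pattern_1..pattern_K`), `P` (K x samples), `K_final`,
#'   `objective_trace`, `n_iterations` (sweeps actually run), `seed`,
#'   `subset_assignments` (`NULL` for single fits), `sample_meta`.
#' @export
factorize_single <- function(expr, n_patterns, n_iterations = 2000,
                             sparsity_penalty = 0, seed = 1, tol = 1e-9,
                             n_restarts = 3, amplitude_cut = 0.1) {
  stopifnot(inherits(expr, "expression_matrix"))
  X <- expr$values
  if (n_patterns < 1 || n_patterns > min(dim(X))) {
    stop("n_patterns must be between 1 and min(genes, samples)", call. = FALSE)
  }
  if (n_restarts > 1) {
    fits <- lapply(seq_len(n_restarts) - 1L, function(r) {
      factorize_single(expr, n_patterns, n_iterations = n_iterations,
                       sparsity_penalty = sparsity_penalty,
                       seed = seed + r * 1000L, tol = tol, n_restarts = 1,
                       amplitude_cut = amplitude_cut)
    })
    objs <- vapply(fits, function(f) utils::tail(f$objective_trace, 1), numeric(1))
    best <- fits[[which.min(objs)]]
    best$seed <- seed
    return(best)
  }
  K <- as.integer(n_patterns)
  lambda <- sparsity_penalty
  mask <- NULL
  mask_A <- NULL
  if (lambda > 0) {
    # warm phase: unpenalized fit, then one exact penalized sweep at the
    # unit-max amplitude scale to screen the pattern-weight support, and
    # an amplitude screen at `amplitude_cut` of each pattern's strongest
    # gene weight. Amplitude sparsity is what restores identifiability:
    # without it, mixtures of the planted programs can fit equally well.
    warm <- factorize_single(expr, n_patterns, n_iterations = n_iterations,
                             sparsity_penalty = 0, seed = seed, tol = tol,
                             n_restarts = 1)
    A <- warm$A
    P <- hals_update_P(X, A, warm$P, lambda)
    mask <- (P > 0) * 1
    mask_A <- (A >= amplitude_cut) * 1
    A <- A * mask_A
  } else {
    local_seed(seed)
    scale0 <- sqrt(mean(X) / max(K, 1) + 1e-12)
    A <- matrix(stats::runif(nrow(X) * K, 0, scale0), nrow(X), K)
    P <- matrix(stats::runif(K * ncol(X), 0, scale0), K, ncol(X))
  }
  trace <- numeric(0)
  obj_prev <- Inf
  for (it in seq_len(n_iterations)) {
    A <- hals_update_A(X, A, P, 0, mask = mask_A)
    P <- hals_update_P(X, A, P, 0, mask = mask)
    obj <- nmf_objective(X, A, P, 0)
    trace[it] <- obj
    if (is.finite(obj_prev) && obj_prev - obj <= tol * max(obj_prev, 1e-300)) {
      obj_prev <- obj
      break
    }
    obj_prev <- obj
  }
  nf <- normalize_factors(A, P)
  dimnames(nf$A) <- list(expr$gene_ids, paste0("pattern_", seq_len(K)))
  dimnames(nf$P) <- list(paste0("pattern_", seq_len(K)), expr$sample_ids)
  new_factorization(nf$A, nf$P, K_final = K, objective_trace = trace,
                    n_iterations = length(trace), seed = seed,
                    subset_assignments = NULL, sample_meta = expr$sample_meta,
                    sparsity_penalty = lambda)
}

new_factorization <- function(A, P, K_final, objective_trace, n_iterations,
                              seed, subset_assignments, sample_meta,
                              sparsity_penalty = 0) {
  structure(list(A = A, P = P, K_final = K_final,
                 objective_trace = objective_trace,
                 n_iterations = n_iterations, seed = seed,
                 subset_assignments = subset_assignments,
                 sample_meta = sample_meta,
                 sparsity_penalty = sparsity_penalty),
            class = "factorization_result")
}

#' @export
print.factorization_result <- function(x, ...) {
  cat(sprintf("<factorization_result> %d genes x %d samples, K_final=%d (%d sweeps, seed %s)\n",
              nrow(x$A), ncol(x$P), x$K_final, x$n_iterations,
              format(x$seed)))
  invisible(x)
}

# non-negative least squares of Y columns on fixed basis A
nnls_columns <- function(A, Y) {
  W <- matrix(0, ncol(A), ncol(Y), dimnames = list(colnames(A), colnames(Y)))
  for (j in seq_len(ncol(Y))) {
    W[, j] <- pracma::lsqnonneg(A, Y[, j])$x
  }
  W
}

#' Consensus factorization across random sample subsets
#'
#' Samples are partitioned into `n_sets` balanced random subsets (the split
#' is keyed to sorted sample identifiers, so results do not depend on input
#' column order), each subset is factorized independently, and the subset
#' gene-weight vectors (amplitude columns, the dimension shared across cell
#' subsets) are pooled and clustered by Pearson correlation with average
#' linkage, cutting at `1 - match_threshold`. Clusters represented in at
#' least `min_subset_fraction` of the subsets become consensus patterns
#' (member mean, rescaled). With consensus gene weights fixed, the pattern
#' matrix is re-learned on all samples by non-negative least squares, and
#' the amplitude matrix receives one final alternating refinement on the
#' full data. Because matching happens across subsets, the final number of
#' patterns may be smaller than the number requested.
#'
#' @inheritParams factorize_single
#' @param n_sets Number of random subsets (>= 2; 12 in the large-data
#'   setting this mirrors, smaller for desk-scale data).
#' @param match_threshold Minimum Pearson correlation for two subset
#'   patterns to be merged (default 0.7).
#' @param min_subset_fraction Minimum fraction of subsets a cluster must
#'   appear in to survive (default 0.5).
#' @param subsets Optional explicit assignment (named integer vector,
#'   sample_id -> subset index) overriding the random split.
#' @return A `factorization_result`; `K_final` may be less than
#'   `n_patterns`, and `subset_assignments` records the split.
#' @export
consensus_factorize <- function(expr, n_patterns, n_sets = 12,
                                n_iterations = 2000, sparsity_penalty = 0,
                                match_threshold = 0.7,
                                min_subset_fraction = 0.5, seed = 1,
                                tol = 1e-9, subsets = NULL,
                                amplitude_cut = 0.1) {
  stopifnot(inherits(expr, "expression_matrix"))
  n <- length(expr$sample_ids)
  if (n_sets < 2) stop("n_sets must be at least 2", call. = FALSE)
  if (floor(n / n_sets) < n_patterns) {
    stop("each random subset must contain at least n_patterns samples", call. = FALSE)
  }
  if (is.null(subsets)) {
    sorted_ids <- sort(expr$sample_ids)
    local_seed(seed)
    perm <- sample(sorted_ids)
    subsets <- stats::setNames(rep(seq_len(n_sets), length.out = n), perm)
  } else {
    if (!all(expr$sample_ids %in% names(subsets))) {
      stop("explicit subsets must cover every sample id", call. = FALSE)
    }
  }
  assign_tab <- tibble::tibble(sample_id = names(subsets),
                               subset = as.integer(unname(subsets)))

  sub_fits <- lapply(seq_len(n_sets), function(s) {
    ids <- sort(names(subsets)[subsets == s])
    sub <- subset_expression(expr, samples = ids)
    factorize_single(sub, n_patterns, n_iterations = n_iterations,
                     sparsity_penalty = sparsity_penalty,
                     seed = seed + s, tol = tol,
                     amplitude_cut = amplitude_cut)
  })

  pooled <- do.call(cbind, lapply(sub_fits, function(f) f$A))
  origin <- rep(seq_len(n_sets), each = n_patterns)
  nz <- apply(pooled, 2, function(x) stats::sd(x) > 0 && max(x) > 0)
  pooled <- pooled[, nz, drop = FALSE]
  origin <- origin[nz]
  if (ncol(pooled) == 0) stop("all subset patterns degenerate", call. = FALSE)

  cors <- stats::cor(pooled)
  d <- stats::as.dist(1 - cors)
  cl <- if (ncol(pooled) > 1) {
    stats::cutree(stats::hclust(d, method = "average"), h = 1 - match_threshold)
  } else c(1L)
  keep_cl <- vapply(split(origin, cl), function(o) {
    length(unique(o)) >= min_subset_fraction * n_sets
  }, logical(1))
  if (!any(keep_cl)) {
    stop("no consensus cluster appears in at least min_subset_fraction of subsets",
         call. = FALSE)
  }
  kept <- as.integer(names(keep_cl)[keep_cl])
  A_cons <- vapply(kept, function(cid) {
    members <- pooled[, cl == cid, drop = FALSE]
    members <- sweep(members, 2, apply(members, 2, max), "/")
    rowMeans(members)
  }, numeric(nrow(pooled)))
  A_cons <- as.matrix(A_cons)
  # order consensus patterns by cluster size (most reproducible first)
  sizes <- vapply(kept, function(cid) sum(cl == cid), integer(1))
  A_cons <- A_cons[, order(-sizes), drop = FALSE]
  K_final <- ncol(A_cons)
  colnames(A_cons) <- paste0("pattern_", seq_len(K_final))
  rownames(A_cons) <- expr$gene_ids

  # re-learn P on all samples with gene weights fixed, then one final
  # alternating refinement of A on the entire dataset
  X <- expr$values
  P <- nnls_columns(A_cons, X)
  A_ref <- hals_update_A(X, A_cons, P, sparsity_penalty)
  P <- hals_update_P(X, A_ref, P, sparsity_penalty)
  nf <- normalize_factors(A_ref, P)
  dimnames(nf$A) <- list(expr$gene_ids, paste0("pattern_", seq_len(K_final)))
  dimnames(nf$P) <- list(paste0("pattern_", seq_len(K_final)), expr$sample_ids)

  traces <- lapply(sub_fits, function(f) f$objective_trace)
  new_factorization(nf$A, nf$P, K_final = K_final,
                    objective_trace = traces,
                    n_iterations = sum(vapply(sub_fits, function(f) f$n_iterations,
                                              integer(1))),
                    seed = seed, subset_assignments = assign_tab,
                    sample_meta = expr$sample_meta,
                    sparsity_penalty = sparsity_penalty)
}

#' Annotate cells by canonical marker gene sets
#'
#' Each cell is labeled with the marker set of maximal mean expression;
#' exact ties are broken alphabetically and flagged; cells in which every
#' marker set has zero mean expression are labeled `"unassigned"`.
#'
#' @param expr An [expression_matrix()].
#' @param marker_table Named list (or `geneset_collection`) mapping cell
#'   type to marker gene symbols.
#' @return A tibble with `sample_id`, `cell_type`, `tie` (logical).
#' @export
annotate_cell_types <- function(expr, marker_table) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (length(marker_table) == 0) stop("empty marker table", call. = FALSE)
  present <- lapply(marker_table, intersect, y = expr$gene_ids)
  absent <- names(marker_table)[vapply(present, length, integer(1)) == 0]
  if (length(absent)) {
    stop("no marker genes present in expression for: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  scores <- vapply(present, function(g) {
    colMeans(expr$values[g, , drop = FALSE])
  }, numeric(length(expr$sample_ids)))
  scores <- matrix(scores, ncol = length(present),
                   dimnames = list(expr$sample_ids, names(present)))
  lab <- character(nrow(scores)); tie <- logical(nrow(scores))
  types_sorted <- sort(colnames(scores))
  for (i in seq_len(nrow(scores))) {
    s <- scores[i, types_sorted]
    if (max(s) <= 0) { lab[i] <- "unassigned"; next }
    best <- names(s)[s == max(s)]
    lab[i] <- best[1]                    # alphabetical tie-break (sorted)
    tie[i] <- length(best) > 1
  }
  tibble::tibble(sample_id = rownames(scores), cell_type = lab, tie = tie)
}
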