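#' Assign marker genes to patterns (the PatternMarker statistic)
#'
#' Each gene's amplitude row is scaled to unit maximum and compared, by
#' Euclidean distance, to each pattern's standard basis vector; the gene is
#' assigned to the nearest pattern and ranked within it by ascending
#' distance. Exact ties are broken toward the lowest pattern index and
#' flagged. All-zero gene rows are excluded and reported; all-zero
#' (degenerate) pattern columns are excluded from assignment and flagged.
#'
#' @param A Non-negative genes-by-K amplitude matrix with dimnames.
#' @param mode `"all"` (default: every retained gene assigned to its nearest
#'   pattern) or `"cut"` (a gene is retained for its assigned pattern only
#'   when it is closer to that basis vector than to the flat, non-specific
#'   profile).
#' @return An object of class `pattern_marker_result`: a tibble with
#'   `gene_id`, `pattern`, `distance`, `rank`, `tie`; attributes
#'   `excluded_genes` (all-zero rows) and `excluded_patterns` (zero
#'   columns).
#' @export
pattern_markers <- function(A, mode = c("all", "cut")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(A), !is.null(rownames(A)), !is.null(colnames(A)))
  if (any(A < 0)) stop("amplitude matrix must be non-negative", call. = FALSE)
  zero_pat <- colnames(A)[apply(A, 2, max) <= 0]
  if (length(zero_pat)) {
    warning("degenerate (all-zero) pattern(s) excluded: ",
            paste(zero_pat, collapse = ", "), call. = FALSE)
  }
  keep_pat <- setdiff(colnames(A), zero_pat)
  if (!length(keep_pat)) stop("no non-degenerate patterns", call. = FALSE)
  Ak <- A[, keep_pat, drop = FALSE]
  rmax <- apply(Ak, 1, max)
  excluded_genes <- rownames(Ak)[rmax <= 0]
  Ak <- Ak[rmax > 0, , drop = FALSE]
  S <- Ak / apply(Ak, 1, max)                      # rows scaled to unit max
  K <- ncol(S)
  # d(g,k) = || scaled row - e_k ||
  D <- vapply(seq_len(K), function(k) {
    e <- numeric(K); e[k] <- 1
    sqrt(rowSums(sweep(S, 2, e, "-")^2))
  }, numeric(nrow(S)))
  D <- matrix(D, nrow = nrow(S),
              dimnames = list(rownames(S), keep_pat))
  assigned <- apply(D, 1, which.min)               # lowest index on ties
  dmin <- D[cbind(seq_len(nrow(D)), assigned)]
  tie <- vapply(seq_len(nrow(D)), function(i) {
    sum(abs(D[i, ] - dmin[i]) < 1e-12) > 1
  }, logical(1))
  res <- tibble::tibble(gene_id = rownames(D),
                        pattern = keep_pat[assigned],
                        distance = dmin, tie = tie)
  if (mode == "cut") {
    flat <- rep(1, K)
    d_flat <- sqrt(rowSums(sweep(S, 2, flat, "-")^2))
    res <- res[res$distance < d_flat, , drop = FALSE]
  }
  res <- res |>
    dplyr::group_by(.data$pattern) |>
    dplyr::arrange(.data$distance, .data$gene_id, .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("gene_id", "pattern", "distance", "rank", "tie")
  attr(res, "excluded_genes") <- excluded_genes
  attr(res, "excluded_patterns") <- zero_pat
  class(res) <- c("pattern_marker_result", class(res))
  res
}

#' Extract the ordered marker list of one pattern
#'
#' @param markers A [pattern_markers()] result.
#' @param pattern Pattern name (e.g. `"pattern_4"`).
#' @param n Optional cap on the number of genes returned.
#' @return Character vector of gene ids, best markers first.
#' @export
markers_for <- function(markers, pattern, n = Inf) {
  sub <- markers[markers$pattern == pattern, , drop = FALSE]
  utils::head(sub$gene_id[order(sub$rank)], n)
}

#' Permutation gene-set enrichment of amplitude columns
#'
#' For each (gene set, pattern) pair the observed statistic is the mean
#' scaled amplitude of the set's genes in that pattern (columns pre-scaled
#' to unit maximum). The null is the same statistic for random gene sets of
#' the same size drawn without replacement from the amplitude's genes; a
#' permutation z-score and one-sided empirical p-value
#' `(1 + #{null >= obs}) / (n_perm + 1)` are reported, with
#' Benjamini-Hochberg adjustment across all testable (set, pattern) pairs.
#' When `exact_if_feasible` and `choose(n_genes, set size) <= 1e5`, full
#' enumeration replaces sampling and `p = #{null >= obs} / #subsets`.
#' Sets with no overlapping genes are reported as `NA` and excluded from
#' the adjustment family.
#'
#' @param A Non-negative genes-by-K amplitude matrix with dimnames.
#' @param sets A `geneset_collection` or named list of gene vectors.
#' @param n_perm Number of random sets per (set size) (default 10000).
#' @param seed Permutation seed (recorded in the result).
#' @param exact_if_feasible Use exhaustive enumeration for small designs.
#' @return An object of class `enrichment_result`: tibble with `gene_set`,
#'   `pattern`, `n_genes`, `statistic`, `z`, `p`, `p_adj`, `method`;
#'   attributes `n_perm`, `seed`.
#' @export
geneset_enrichment <- function(A, sets, n_perm = 10000, seed = 1,
                               exact_if_feasible = TRUE) {
  stopifnot(is.matrix(A), !is.null(rownames(A)), !is.null(colnames(A)))
  if (any(A < 0)) stop("amplitude matrix must be non-negative", call. = FALSE)
  cmax <- apply(A, 2, max)
  cmax[cmax <= 0] <- 1
  S <- sweep(A, 2, cmax, "/")
  genes <- rownames(S)
  overlaps <- lapply(sets, intersect, y = genes)
  if (all(vapply(overlaps, length, integer(1)) == 0)) {
    stop("no gene set overlaps the amplitude matrix", call. = FALSE)
  }
  local_seed(seed)
  rows <- list()
  for (nm in names(sets)) {
    g <- overlaps[[nm]]
    m <- length(g)
    if (m == 0) {
      rows[[nm]] <- tibble::tibble(gene_set = nm, pattern = colnames(S),
                                   n_genes = 0L, statistic = NA_real_,
                                   z = NA_real_, p = NA_real_,
                                   method = "no_overlap")
      next
    }
    obs <- colMeans(S[g, , drop = FALSE])
    exact <- exact_if_feasible && choose(length(genes), m) <= 1e5
    if (exact) {
      combos <- utils::combn(length(genes), m)
      null_stats <- vapply(seq_len(ncol(combos)), function(j) {
        colMeans(S[combos[, j], , drop = FALSE])
      }, numeric(ncol(S)))
      null_stats <- matrix(null_stats, nrow = ncol(S))   # K x n_null
      p <- rowMeans(null_stats >= obs + 0)
      method <- "exact"
    } else {
      idx <- replicate(n_perm, sample.int(length(genes), m))
      idx <- matrix(idx, nrow = m)
      null_stats <- vapply(seq_len(n_perm), function(j) {
        colMeans(S[idx[, j], , drop = FALSE])
      }, numeric(ncol(S)))
      null_stats <- matrix(null_stats, nrow = ncol(S))
      p <- (1 + rowSums(null_stats >= obs + 0)) / (n_perm + 1)
      method <- "sampled"
    }
    mu <- rowMeans(null_stats)
    sdv <- apply(null_stats, 1, stats::sd)
    z <- ifelse(sdv > 0, (obs - mu) / sdv, 0)
    rows[[nm]] <- tibble::tibble(gene_set = nm, pattern = colnames(S),
                                 n_genes = m, statistic = unname(obs),
                                 z = unname(z), p = unname(p),
                                 method = method)
  }
  res <- dplyr::bind_rows(rows)
  res$p_adj <- NA_real_
  testable <- !is.na(res$p)
  res$p_adj[testable] <- bh_adjust(res$p[testable])
  attr(res, "n_perm") <- n_perm
  attr(res, "seed") <- seed
  class(res) <- c("enrichment_result", class(res))
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper over `stats::p.adjust(method = "BH")`:
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1, input order preserved.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, elementwise >= the input.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must be in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}
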