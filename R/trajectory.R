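#' Order cells along a kNN-geodesic pseudotime
#'
#' Builds a k-nearest-neighbor graph on the first principal components of
#' the cell subset (or on a supplied 2-D embedding), chooses the root in
#' the low-activation region — the minimum-weight cell of the lowest-weight
#' decile, ties broken toward the decile's embedding medoid — and assigns
#' each cell the min-max-scaled graph shortest-path (geodesic) distance
#' from the root. Pseudotime is invariant to global rescaling of the
#' embedding.
#'
#' @param expr An [expression_matrix()] of the cell subset (>= 10 cells),
#'   or `NULL` when `embedding` is supplied.
#' @param pattern_weights Named numeric vector of the guiding pattern's
#'   weights (names = sample ids) used for root selection.
#' @param k_neighbors Neighbors per cell in the graph (default 15).
#' @param n_pcs Number of principal components for the internal embedding
#'   (default 2).
#' @param embedding Optional externally computed cells-by-2 coordinate
#'   matrix with rownames; skips the internal PCA.
#' @return An object of class `pseudotime_result`: tibble with `sample_id`,
#'   `pseudotime` (in [0, 1], root at 0); attributes `root_id`,
#'   `embedding`.
#' @export
order_cells_pseudotime <- function(expr, pattern_weights, k_neighbors = 15,
                                   n_pcs = 2, embedding = NULL) {
  if (is.null(embedding)) {
    stopifnot(inherits(expr, "expression_matrix"))
    if (length(expr$sample_ids) < 10) stop("need at least 10 cells", call. = FALSE)
    pc <- stats::prcomp(t(expr$values), center = TRUE, scale. = FALSE,
                        rank. = n_pcs)
    embedding <- pc$x
    rownames(embedding) <- expr$sample_ids
  } else {
    embedding <- as.matrix(embedding)
    if (is.null(rownames(embedding))) stop("embedding needs cell rownames", call. = FALSE)
    if (nrow(embedding) < 10) stop("need at least 10 cells", call. = FALSE)
  }
  ids <- rownames(embedding)
  miss <- setdiff(ids, names(pattern_weights))
  if (length(miss)) stop("pattern_weights missing for some cells", call. = FALSE)
  w <- pattern_weights[ids]
  n <- length(ids)
  k <- min(k_neighbors, n - 1)

  D <- as.matrix(stats::dist(embedding))
  edges <- list(); ew <- list()
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[2:(k + 1)]
    edges[[i]] <- rbind(i, nb)
    ew[[i]] <- D[i, nb]
  }
  el <- t(do.call(cbind, edges))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::E(g)$weight <- unlist(ew)
  g <- igraph::simplify(g, edge.attr.comb = "min")
  if (igraph::components(g)$no > 1) {
    stop("kNN graph is disconnected; increase k_neighbors", call. = FALSE)
  }

  # root: lowest-weight decile; min weight wins, ties resolved toward the
  # decile's medoid in the embedding
  dec <- which(w <= stats::quantile(w, 0.1, type = 7))
  Dd <- D[dec, dec, drop = FALSE]
  medoid <- dec[which.min(rowSums(Dd))]
  cand <- dec[w[dec] == min(w[dec])]
  root <- cand[which.min(D[cand, medoid])]

  pt <- as.numeric(igraph::distances(g, v = root)[1, ])
  rng <- range(pt)
  pt <- if (diff(rng) > 0) (pt - rng[1]) / diff(rng) else pt * 0
  res <- tibble::tibble(sample_id = ids, pseudotime = pt)
  attr(res, "root_id") <- ids[root]
  attr(res, "embedding") <- embedding
  class(res) <- c("pseudotime_result", class(res))
  res
}

#' Associate genes with pseudotime
#'
#' Per-gene Spearman correlation of expression with pseudotime, BH-adjusted
#' q-values, selection at `q < q_cutoff`. Constant gene rows are skipped
#' with a flag rather than dropped silently.
#'
#' @param expr An [expression_matrix()] over the same cells.
#' @param pseudotime A [order_cells_pseudotime()] result (or tibble with
#'   `sample_id`, `pseudotime`).
#' @param q_cutoff Selection threshold on the BH q-value (default 0.01).
#' @return A tibble with `gene_id`, `rho`, `p`, `q`, `selected`,
#'   `constant`.
#' @export
pseudotime_gene_association <- function(expr, pseudotime, q_cutoff = 0.01) {
  stopifnot(inherits(expr, "expression_matrix"))
  pt <- pseudotime$pseudotime[match(expr$sample_ids, pseudotime$sample_id)]
  if (any(is.na(pt))) stop("pseudotime missing for some cells", call. = FALSE)
  rows <- lapply(expr$gene_ids, function(gid) {
    v <- expr$values[gid, ]
    if (stats::sd(v) == 0) {
      return(tibble::tibble(gene_id = gid, rho = NA_real_, p = NA_real_,
                            constant = TRUE))
    }
    ht <- suppressWarnings(stats::cor.test(v, pt, method = "spearman", exact = FALSE))
    tibble::tibble(gene_id = gid, rho = unname(ht$estimate), p = ht$p.value,
                   constant = FALSE)
  })
  res <- dplyr::bind_rows(rows)
  res$q <- NA_real_
  ok <- !res$constant
  # perfect monotone genes yield asymptotic p = 0; clamp for the step-up
  res$p[ok] <- pmax(res$p[ok], .Machine$double.xmin)
  res$q[ok] <- bh_adjust(res$p[ok])
  res$selected <- !is.na(res$q) & res$q < q_cutoff
  res |> dplyr::select("gene_id", "rho", "p", "q", "selected", "constant")
}

#' Intersect pseudotime-associated genes with a pattern's markers
#'
#' @param selected_genes Genes significantly associated with pseudotime.
#' @param marker_genes Marker genes of the pattern of interest.
#' @return Sorted character vector (possibly empty) of the intersection;
#'   its size is reported in the `n` attribute.
#' @export
intersect_with_markers <- function(selected_genes, marker_genes) {
  if (length(selected_genes) == 0 || length(marker_genes) == 0) {
    stop("both gene lists must be non-empty", call. = FALSE)
  }
  out <- sort(intersect(selected_genes, marker_genes))
  attr(out, "n") <- length(out)
  out
}
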