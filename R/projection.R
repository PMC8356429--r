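#' Align source amplitudes and target expression on shared (homologous) genes
#'
#' Restricts both objects to the homolog-mapped genes present on both sides,
#' in identical (source-amplitude) order, so the projection regression is
#' well posed. With `homologs = NULL` the identity map on shared gene ids is
#' used. The result does not depend on the target's gene order.
#'
#' @param A_source Genes-by-K amplitude matrix with dimnames.
#' @param expr_target Target [expression_matrix()].
#' @param homologs A `homolog_map` tibble (`source_gene`, `target_gene`) or
#'   `NULL` for the identity map.
#' @return List with `A_sub`, `Y_sub` (same row order), `genes_used`,
#'   `genes_dropped`.
#' @export
align_features <- function(A_source, expr_target, homologs = NULL) {
  stopifnot(is.matrix(A_source), !is.null(rownames(A_source)))
  stopifnot(inherits(expr_target, "expression_matrix"))
  src <- rownames(A_source)
  if (is.null(homologs)) {
    homologs <- tibble::tibble(source_gene = src, target_gene = src)
  }
  if (anyDuplicated(homologs$source_gene) || anyDuplicated(homologs$target_gene)) {
    stop("homolog map must be one-to-one; canonicalize with homolog_map()", call. = FALSE)
  }
  map <- homologs[homologs$source_gene %in% src &
                    homologs$target_gene %in% expr_target$gene_ids, , drop = FALSE]
  # deterministic order: follow the source amplitude's gene order
  map <- map[order(match(map$source_gene, src)), , drop = FALSE]
  genes_used <- nrow(map)
  if (genes_used < ncol(A_source)) {
    stop("fewer aligned genes (", genes_used, ") than patterns (",
         ncol(A_source), ")", call. = FALSE)
  }
  A_sub <- A_source[map$source_gene, , drop = FALSE]
  Y_sub <- expr_target$values[map$target_gene, , drop = FALSE]
  list(A_sub = A_sub, Y_sub = Y_sub, genes_used = genes_used,
       genes_dropped = length(src) - genes_used)
}

#' Project a target dataset into a learned pattern space
#'
#' Estimates, for every target sample, the usage of each source pattern by
#' regressing the sample's expression over the aligned genes onto the fixed
#' source gene weights: `min_w ||y - A w||_2` (ordinary least squares via
#' QR, or non-negativity-constrained). Optional per-gene mean-centering of
#' the target is the default for bulk and panel wrappers.
#'
#' @param A_source Genes-by-K amplitude matrix.
#' @param expr_target Target [expression_matrix()] (same space the source
#'   was trained on).
#' @param homologs Optional `homolog_map`; `NULL` = identity on shared ids.
#' @param mode `"ols"` or `"nnls"`.
#' @param center_genes Mean-center each aligned target gene first.
#' @param drop_unidentifiable Drop patterns whose aligned gene weights are
#'   all (near) zero instead of erroring; their rows are returned as `NA`
#'   and listed in the `unidentifiable` attribute.
#' @return An object of class `projection_result`: `P_new` (K x target
#'   samples), `genes_used`, `genes_dropped`, `mode`, `centered`,
#'   `sample_meta` of the target.
#' @export
project <- function(A_source, expr_target, homologs = NULL,
                    mode = c("ols", "nnls"), center_genes = FALSE,
                    drop_unidentifiable = FALSE) {
  mode <- match.arg(mode)
  al <- align_features(A_source, expr_target, homologs)
  A_sub <- al$A_sub
  Y <- al$Y_sub
  if (center_genes) Y <- Y - rowMeans(Y)
  unident <- character(0)
  pat_all <- colnames(A_sub)
  if (drop_unidentifiable) {
    zero <- apply(A_sub, 2, function(a) max(abs(a)) < 1e-10)
    unident <- pat_all[zero]
    A_sub <- A_sub[, !zero, drop = FALSE]
    if (ncol(A_sub) == 0) stop("no identifiable patterns on this panel", call. = FALSE)
  }
  qrA <- qr(A_sub)
  if (qrA$rank < ncol(A_sub)) {
    bad <- colnames(A_sub)[qrA$pivot[(qrA$rank + 1):ncol(A_sub)]]
    stop("aligned amplitude matrix is rank-deficient; collinear pattern(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  W <- if (mode == "ols") {
    qr.coef(qrA, Y)
  } else {
    nnls_columns(A_sub, Y)
  }
  W <- matrix(W, nrow = ncol(A_sub),
              dimnames = list(colnames(A_sub), expr_target$sample_ids))
  if (length(unident)) {
    full <- matrix(NA_real_, length(pat_all), ncol(W),
                   dimnames = list(pat_all, colnames(W)))
    full[rownames(W), ] <- W
    W <- full
  }
  structure(list(P_new = W, genes_used = al$genes_used,
                 genes_dropped = al$genes_dropped, mode = mode,
                 centered = center_genes,
                 unidentifiable = unident,
                 sample_meta = expr_target$sample_meta),
            class = "projection_result")
}

#' @export
print.projection_result <- function(x, ...) {
  cat(sprintf("<projection_result> %d patterns x %d samples (%s%s, %d genes used, %d dropped)\n",
              nrow(x$P_new), ncol(x$P_new), x$mode,
              if (x$centered) ", centered" else "", x$genes_used, x$genes_dropped))
  if (length(x$unidentifiable)) {
    cat("unidentifiable pattern(s):", paste(x$unidentifiable, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Project bulk expression (per-gene centering on by default)
#'
#' @inheritParams project
#' @param ... Passed to [project()].
#' @return A `projection_result`.
#' @export
project_bulk <- function(A_source, expr_target, homologs = NULL,
                         mode = "ols", ...) {
  project(A_source, expr_target, homologs = homologs, mode = mode,
          center_genes = TRUE, ...)
}

#' Project a reduced feature panel (CyTOF-like)
#'
#' Feature intersection by name, per-gene centering on, and patterns with no
#' loading on the panel flagged unidentifiable rather than erroring.
#'
#' @inheritParams project
#' @param ... Passed to [project()].
#' @return A `projection_result`.
#' @export
project_panel <- function(A_source, expr_target, homologs = NULL,
                          mode = "ols", ...) {
  res <- project(A_source, expr_target, homologs = homologs, mode = mode,
                 center_genes = TRUE, drop_unidentifiable = TRUE, ...)
  if (length(res$unidentifiable)) {
    warning("pattern(s) unidentifiable on this panel: ",
            paste(res$unidentifiable, collapse = ", "), call. = FALSE)
  }
  res
}
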