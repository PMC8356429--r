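#' Construct an expression matrix object
#'
#' The central data container of the package: a non-negative gene-by-sample
#' matrix with gene and sample identifiers, a per-sample metadata table, and a
#' flag recording whether values are raw counts or log2-transformed.
#' Factorization, projection and gating all operate on this object.
#'
#' @param values Numeric matrix, genes in rows, samples (cells) in columns.
#'   All entries must be finite and non-negative.
#' @param gene_ids Character vector of unique gene identifiers, one per row.
#'   Defaults to `rownames(values)`.
#' @param sample_ids Character vector of unique sample/cell identifiers, one
#'   per column. Defaults to `colnames(values)`.
#' @param sample_meta Data frame of per-sample annotations (e.g. `cell_type`,
#'   `treatment`, `response`), one row per sample in the same order as
#'   `sample_ids`. May be `NULL`.
#' @param space Either `"counts"` or `"log2"`; the scale the values live on.
#'
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `gene_ids`, `sample_ids`, `sample_meta` (a tibble), `space`.
#' @export
#' @examples
#' m <- matrix(abs(rnorm(6)), 3, 2,
#'             dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' expr <- expression_matrix(m, space = "log2")
#' dim(expr)
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values),
                              sample_meta = NULL,
                              space = c("log2", "counts")) {
  space <- match.arg(space)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("gene and sample identifiers are required (row/column names or explicit)",
         call. = FALSE)
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values)) {
    stop("length(gene_ids) must equal nrow(values)", call. = FALSE)
  }
  if (length(sample_ids) != ncol(values)) {
    stop("length(sample_ids) must equal ncol(values)", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene_ids: ",
         paste(utils::head(unique(gene_ids[duplicated(gene_ids)]), 3), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample_ids: ",
         paste(utils::head(unique(sample_ids[duplicated(sample_ids)]), 3), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(values))) stop("non-finite values in expression matrix", call. = FALSE)
  if (any(values < 0)) stop("negative values in expression matrix", call. = FALSE)
  dimnames(values) <- list(gene_ids, sample_ids)
  if (!is.null(sample_meta)) {
    sample_meta <- tibble::as_tibble(sample_meta)
    if (nrow(sample_meta) != length(sample_ids)) {
      stop("sample_meta must have one row per sample", call. = FALSE)
    }
    if (!"sample_id" %in% names(sample_meta)) {
      sample_meta <- dplyr::bind_cols(tibble::tibble(sample_id = sample_ids), sample_meta)
    }
  } else {
    sample_meta <- tibble::tibble(sample_id = sample_ids)
  }
  structure(
    list(values = values, gene_ids = gene_ids, sample_ids = sample_ids,
         sample_meta = sample_meta, space = space),
    class = "expression_matrix"
  )
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples [%s space]\n",
              nrow(x$values), ncol(x$values), x$space))
  extra <- setdiff(names(x$sample_meta), "sample_id")
  if (length(extra)) cat("sample_meta:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' Subset an expression matrix by genes and/or samples
#'
#' @param x An `expression_matrix`.
#' @param genes,samples Character identifiers or integer/logical indices;
#'   `NULL` keeps everything.
#' @return A new `expression_matrix` restricted accordingly; metadata rows
#'   follow the samples.
#' @export
subset_expression <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "expression_matrix"))
  gi <- if (is.null(genes)) seq_along(x$gene_ids) else {
    if (is.character(genes)) {
      miss <- setdiff(genes, x$gene_ids)
      if (length(miss)) stop("genes not present: ", paste(utils::head(miss, 5), collapse = ", "),
                             call. = FALSE)
      match(genes, x$gene_ids)
    } else which(seq_along(x$gene_ids) %in% seq_along(x$gene_ids)[genes])
  }
  si <- if (is.null(samples)) seq_along(x$sample_ids) else {
    if (is.character(samples)) {
      miss <- setdiff(samples, x$sample_ids)
      if (length(miss)) stop("samples not present: ", paste(utils::head(miss, 5), collapse = ", "),
                             call. = FALSE)
      match(samples, x$sample_ids)
    } else which(seq_along(x$sample_ids) %in% seq_along(x$sample_ids)[samples])
  }
  expression_matrix(x$values[gi, si, drop = FALSE],
                    gene_ids = x$gene_ids[gi], sample_ids = x$sample_ids[si],
                    sample_meta = x$sample_meta[si, , drop = FALSE],
                    space = x$space)
}

#' Convert an expression matrix to a long tibble
#'
#' One row per (gene, sample) pair, joined with the sample metadata, for use
#' with dplyr/ggplot2.
#'
#' @param x An `expression_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `gene_id`, `sample_id`, `value`, plus the
#'   metadata columns.
#' @export
tidy.expression_matrix <- function(x, ...) {
  long <- tibble::tibble(
    gene_id = rep(x$gene_ids, times = length(x$sample_ids)),
    sample_id = rep(x$sample_ids, each = length(x$gene_ids)),
    value = as.vector(x$values)
  )
  dplyr::left_join(long, x$sample_meta, by = "sample_id")
}
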