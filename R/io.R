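#' Read an expression matrix from disk
#'
#' Supports the 10x-style Matrix Market layout (`matrix.mtx` with sibling
#' `genes.tsv` and `barcodes.tsv`: genes are rows, cells are columns, 1-based
#' indices) and dense TSV/CSV (first column gene ids, header sample ids).
#'
#' @param path Path to the `.mtx` file or the dense table.
#' @param format `"mtx"` or `"tsv"`. Guessed from the extension by default.
#' @param space Scale of the stored values, `"counts"` or `"log2"`.
#' @param genes_file,barcodes_file Optional explicit sibling paths for the
#'   mtx layout; default to `genes.tsv` / `barcodes.tsv` next to the matrix.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, format = c("auto", "mtx", "tsv"),
                            space = c("log2", "counts"),
                            genes_file = NULL, barcodes_file = NULL) {
  format <- match.arg(format)
  space <- match.arg(space)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "mtx") {
    dirn <- dirname(path)
    genes_file <- genes_file %||% file.path(dirn, "genes.tsv")
    barcodes_file <- barcodes_file %||% file.path(dirn, "barcodes.tsv")
    if (!file.exists(genes_file)) stop("missing sibling gene file: ", genes_file, call. = FALSE)
    if (!file.exists(barcodes_file)) stop("missing sibling barcode file: ", barcodes_file, call. = FALSE)
    m <- as.matrix(Matrix::readMM(path))
    storage.mode(m) <- "double"
    genes <- readr::read_tsv(genes_file, col_names = FALSE, show_col_types = FALSE)[[1]]
    barcodes <- readr::read_tsv(barcodes_file, col_names = FALSE, show_col_types = FALSE)[[1]]
    if (length(genes) != nrow(m) || length(barcodes) != ncol(m)) {
      stop("gene/barcode file lengths do not match matrix dimensions", call. = FALSE)
    }
    expression_matrix(m, gene_ids = genes, sample_ids = barcodes, space = space)
  } else {
    delim <- if (grepl("\\.csv$", path)) "," else "\t"
    tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                             progress = FALSE)
    gene_ids <- as.character(tab[[1]])
    vals <- tab[, -1, drop = FALSE]
    bad <- !vapply(vals, is.numeric, logical(1))
    if (any(bad)) {
      stop("non-numeric expression columns: ",
           paste(utils::head(names(vals)[bad], 5), collapse = ", "), call. = FALSE)
    }
    m <- as.matrix(vals)
    expression_matrix(m, gene_ids = gene_ids, sample_ids = colnames(vals),
                      space = space)
  }
}

#' Write an expression matrix to disk
#'
#' @param expr An [expression_matrix()].
#' @param path Output path; `.mtx` writes Matrix Market with sibling
#'   `genes.tsv`/`barcodes.tsv`, anything else a dense TSV.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (grepl("\\.mtx$", path)) {
    Matrix::writeMM(Matrix::Matrix(expr$values, sparse = TRUE), path)
    dirn <- dirname(path)
    readr::write_tsv(tibble::tibble(x = expr$gene_ids),
                     file.path(dirn, "genes.tsv"), col_names = FALSE)
    readr::write_tsv(tibble::tibble(x = expr$sample_ids),
                     file.path(dirn, "barcodes.tsv"), col_names = FALSE)
  } else {
    tab <- tibble::as_tibble(expr$values, .name_repair = "minimal")
    tab <- dplyr::bind_cols(tibble::tibble(gene_id = expr$gene_ids), tab)
    readr::write_tsv(tab, path)
  }
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: each tab-separated line is `name<TAB>description<TAB>member...`.
#' The description is discarded and duplicate members within a set are
#' de-duplicated. Lines with fewer than three fields and duplicated set names
#' are errors.
#'
#' @param path Path to a `.gmt` file.
#' @return A named list of character vectors (class `geneset_collection`).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, integer(1)) < 3L
  if (any(short)) {
    stop("GMT line(s) with fewer than 3 fields: line ",
         paste(utils::head(which(short), 5), collapse = ", "), call. = FALSE)
  }
  nms <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nms)) {
    stop("duplicate gene set name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nms
  geneset_collection(sets)
}

#' Construct a validated gene-set collection
#'
#' @param sets Named list of character vectors; names unique, no empty sets.
#' @return The list with class `geneset_collection`.
#' @export
geneset_collection <- function(sets) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("all gene sets must be named", call. = FALSE)
  }
  if (anyDuplicated(names(sets))) stop("gene set names must be unique", call. = FALSE)
  if (any(vapply(sets, length, integer(1)) == 0L)) {
    stop("empty gene sets are not allowed", call. = FALSE)
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  structure(sets, class = "geneset_collection")
}

#' Write a gene-set collection as GMT
#'
#' @param sets A `geneset_collection` (or plain named list).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(n) {
    paste(c(n, "na", sets[[n]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-sample clinical table
#'
#' Expects a TSV with columns `sample_id`, `os_time` (days), `os_event`
#' (0/1), `age`, and optionally `response` (`responder`/`non-responder`/NA)
#' and `treatment`. Rows with missing survival fields are kept and flagged in
#' the `complete_survival` column rather than dropped; downstream analyses
#' exclude them only where the affected quantity needs them.
#'
#' @param path Path to the TSV.
#' @return A tibble of class `clinical_table`.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  clinical_table(tab)
}

#' Validate a clinical table
#'
#' @param tab Data frame with at least `sample_id`, `os_time`, `os_event`, `age`.
#' @return A tibble of class `clinical_table` with a `complete_survival` flag.
#' @export
clinical_table <- function(tab) {
  tab <- tibble::as_tibble(tab)
  required <- c("sample_id", "os_time", "os_event", "age")
  miss <- setdiff(required, names(tab))
  if (length(miss)) stop("missing required clinical column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(tab$sample_id)) stop("duplicate sample_id in clinical table", call. = FALSE)
  ev <- tab$os_event[!is.na(tab$os_event)]
  if (!all(ev %in% c(0, 1))) stop("os_event must be 0 or 1", call. = FALSE)
  ot <- tab$os_time[!is.na(tab$os_time)]
  if (any(ot < 0)) stop("os_time must be non-negative", call. = FALSE)
  if (!"response" %in% names(tab)) tab$response <- NA_character_
  if (!"treatment" %in% names(tab)) tab$treatment <- NA_character_
  badresp <- !tab$response %in% c("responder", "non-responder", NA)
  if (any(badresp)) stop("response must be responder/non-responder/NA", call. = FALSE)
  tab$complete_survival <- !is.na(tab$os_time) & !is.na(tab$os_event)
  class(tab) <- c("clinical_table", class(tab))
  tab
}

#' Read and canonicalize a homolog mapping table
#'
#' TSV with columns `source_gene`, `target_gene`. Many-to-many entries are
#' resolved by keeping only pairs whose source AND target each appear exactly
#' once in the table (the unambiguous one-to-one subset); the number of
#' dropped pairs is recorded in the `dropped_pairs` attribute and messaged.
#'
#' @param path Path to the TSV.
#' @return A tibble of class `homolog_map` with columns `source_gene`,
#'   `target_gene`, attribute `dropped_pairs`.
#' @export
read_homolog_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  homolog_map(tab)
}

#' Canonicalize a homolog table to its one-to-one subset
#'
#' @param tab Data frame with `source_gene` and `target_gene` columns.
#' @return A `homolog_map` tibble (one-to-one pairs only).
#' @export
homolog_map <- function(tab) {
  tab <- tibble::as_tibble(tab)
  miss <- setdiff(c("source_gene", "target_gene"), names(tab))
  if (length(miss)) stop("missing homolog column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  n0 <- nrow(tab)
  keep <- tab |>
    dplyr::add_count(.data$source_gene, name = ".ns") |>
    dplyr::add_count(.data$target_gene, name = ".nt") |>
    dplyr::filter(.data$.ns == 1L, .data$.nt == 1L) |>
    dplyr::select("source_gene", "target_gene")
  dropped <- n0 - nrow(keep)
  if (dropped > 0) {
    message(dropped, " ambiguous homolog pair(s) dropped (non one-to-one)")
  }
  attr(keep, "dropped_pairs") <- dropped
  class(keep) <- c("homolog_map", class(keep))
  keep
}

#' Write a genes-by-K or K-by-samples matrix as TSV with pattern headers
#'
#' @param m Matrix with dimnames.
#' @param path Output path.
#' @param id_col Name of the first (identifier) column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, id_col = "id") {
  tab <- tibble::as_tibble(m, .name_repair = "minimal")
  tab <- dplyr::bind_cols(stats::setNames(tibble::tibble(rownames(m)), id_col), tab)
  readr::write_tsv(tab, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
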