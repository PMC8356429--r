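#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a factorization result into a long tibble
#'
#' @param x A `factorization_result`.
#' @param matrix `"P"` (per-cell pattern weights, joined with the sample
#'   metadata) or `"A"` (per-gene amplitudes).
#' @param ... Unused.
#' @return A tibble: for `"P"`, columns `sample_id`, `pattern`, `weight`
#'   plus metadata; for `"A"`, columns `gene_id`, `pattern`, `amplitude`.
#' @export
tidy.factorization_result <- function(x, matrix = c("P", "A"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "P") {
    long <- tibble::tibble(
      sample_id = rep(colnames(x$P), each = nrow(x$P)),
      pattern = rep(rownames(x$P), times = ncol(x$P)),
      weight = as.vector(x$P)
    )
    if (!is.null(x$sample_meta)) {
      long <- dplyr::left_join(long, x$sample_meta, by = "sample_id")
    }
    long
  } else {
    tibble::tibble(
      gene_id = rep(rownames(x$A), times = ncol(x$A)),
      pattern = rep(colnames(x$A), each = nrow(x$A)),
      amplitude = as.vector(x$A)
    )
  }
}

#' One-row summary of a factorization
#'
#' @param x A `factorization_result`.
#' @param ... Unused.
#' @return A tibble with `K_final`, `n_iterations`, `final_objective`,
#'   `sparsity_penalty`, `seed`.
#' @export
glance.factorization_result <- function(x, ...) {
  tr <- x$objective_trace
  final_obj <- if (is.list(tr)) {
    sum(vapply(tr, function(t) utils::tail(t, 1), numeric(1)))
  } else utils::tail(tr, 1)
  tibble::tibble(K_final = x$K_final, n_iterations = x$n_iterations,
                 final_objective = final_obj,
                 sparsity_penalty = x$sparsity_penalty, seed = x$seed)
}

#' Tidy a projection result into a long tibble
#'
#' @param x A `projection_result`.
#' @param ... Unused.
#' @return A tibble with `sample_id`, `pattern`, `weight`, plus target
#'   sample metadata.
#' @export
tidy.projection_result <- function(x, ...) {
  long <- tibble::tibble(
    sample_id = rep(colnames(x$P_new), each = nrow(x$P_new)),
    pattern = rep(rownames(x$P_new), times = ncol(x$P_new)),
    weight = as.vector(x$P_new)
  )
  if (!is.null(x$sample_meta)) {
    long <- dplyr::left_join(long, x$sample_meta, by = "sample_id")
  }
  long
}

#' @rdname tidy.projection_result
#' @export
glance.projection_result <- function(x, ...) {
  tibble::tibble(n_patterns = nrow(x$P_new), n_samples = ncol(x$P_new),
                 genes_used = x$genes_used, genes_dropped = x$genes_dropped,
                 mode = x$mode, centered = x$centered,
                 n_unidentifiable = length(x$unidentifiable))
}

#' Tidy an ROC result (the curve) and glance (the AUC)
#'
#' @param x A `roc_result`.
#' @param ... Unused.
#' @return `tidy()`: the curve tibble (`threshold`, `tpr`, `fpr`);
#'   `glance()`: one row with `auc`, `n_pos`, `n_neg`.
#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @rdname tidy.roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Tidy a Cox fit (per-covariate table) and glance (fit summary)
#'
#' @param x A `cox_result`.
#' @param ... Unused.
#' @return `tidy()`: tibble with one row per covariate; `glance()`: one row
#'   with `n`, `n_events`, `converged`.
#' @export
tidy.cox_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "cox_result")
  attr(out, "fit") <- NULL
  tibble::as_tibble(out)
}

#' @rdname tidy.cox_result
#' @export
glance.cox_result <- function(x, ...) {
  tibble::tibble(n = attr(x, "n"), n_events = attr(x, "n_events"),
                 converged = attr(x, "converged"))
}
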