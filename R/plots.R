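#' ROC curve plot
#'
#' @param object A `roc_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False-positive rate", y = "True-positive rate",
                  title = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Boxplot of one pattern's weights by group
#'
#' The figure-style view of treatment-associated pattern usage: per-cell
#' weights of one pattern, grouped (e.g. by treatment), with jittered
#' points.
#'
#' @param data Long tibble as produced by [tidy.factorization_result()] or
#'   [tidy.projection_result()].
#' @param pattern Pattern name to show.
#' @param group Column (tidy-eval) holding the grouping label.
#' @return A ggplot.
#' @export
plot_pattern_weights <- function(data, pattern, group) {
  sub <- data[data$pattern == pattern, , drop = FALSE]
  ggplot2::ggplot(sub, ggplot2::aes(x = {{ group }}, y = .data$weight,
                                    fill = {{ group }})) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.15, size = 0.4, alpha = 0.4) +
    ggplot2::labs(y = paste(pattern, "weight"), x = NULL) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Objective trace of a factorization
#'
#' @param fit A `factorization_result` (single fit, or consensus with
#'   per-subset traces).
#' @return A ggplot of the (per-subset) objective over sweeps.
#' @export
plot_objective <- function(fit) {
  tr <- fit$objective_trace
  df <- if (is.list(tr)) {
    dplyr::bind_rows(lapply(seq_along(tr), function(s) {
      tibble::tibble(subset = factor(s), sweep = seq_along(tr[[s]]),
                     objective = tr[[s]])
    }))
  } else {
    tibble::tibble(subset = factor(1), sweep = seq_along(tr), objective = tr)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sweep, y = .data$objective,
                                   colour = .data$subset)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "sweep", y = "penalized objective") +
    ggplot2::theme_minimal()
}

#' Pseudotime versus pattern weight
#'
#' @param pseudotime A [order_cells_pseudotime()] result.
#' @param pattern_weights Named numeric vector over the same cells.
#' @return A ggplot of weight against pseudotime.
#' @export
plot_pseudotime <- function(pseudotime, pattern_weights) {
  pt_vals <- pseudotime$pseudotime
  w_vals <- pattern_weights[pseudotime$sample_id]
  df <- tibble::tibble(pseudotime = pt_vals, weight = w_vals)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pseudotime, y = .data$weight)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.5) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(x = "pseudotime", y = "pattern weight") +
    ggplot2::theme_minimal()
}
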