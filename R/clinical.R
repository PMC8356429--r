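#' Gate cells on required and excluded transcripts
#'
#' Implements the literal gating rule used for NK-cell selection: a cell
#' passes when every required gene is expressed (value > 0) and every
#' excluded gene is absent (value == 0), on the log2(count+1) scale.
#' Thresholds are configurable.
#'
#' @param expr An [expression_matrix()].
#' @param required_genes Genes that must be expressed (non-empty).
#' @param excluded_genes Genes that must be absent.
#' @param expressed_above Expression threshold for "expressed" (default 0).
#' @param absent_at Value counted as "absent" (default 0).
#' @return A tibble with `sample_id` and logical `pass`.
#' @export
gate_cells <- function(expr, required_genes, excluded_genes = character(),
                       expressed_above = 0, absent_at = 0) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (length(required_genes) == 0) stop("required gene list must be non-empty", call. = FALSE)
  all_genes <- c(required_genes, excluded_genes)
  miss <- setdiff(all_genes, expr$gene_ids)
  if (length(miss)) {
    stop("gating gene(s) absent from expression matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  req <- expr$values[required_genes, , drop = FALSE] > expressed_above
  pass <- apply(req, 2, all)
  if (length(excluded_genes)) {
    exc <- expr$values[excluded_genes, , drop = FALSE] == absent_at
    pass <- pass & apply(exc, 2, all)
  }
  tibble::tibble(sample_id = expr$sample_ids, pass = unname(pass))
}

star_code <- function(p) {
  dplyr::case_when(is.na(p) ~ "", p < 0.001 ~ "***", p < 0.01 ~ "**",
                   p < 0.05 ~ "*", TRUE ~ "ns")
}

#' Pairwise group comparison of pattern weights
#'
#' Two-sided pairwise tests of a weight column between all group pairs
#' (Wilcoxon rank-sum by default, exact where possible; Welch t-test behind
#' the `test` flag), Benjamini-Hochberg adjusted across pairs, with the
#' figure-style star coding (`*` p<0.05, `**` p<0.01, `***` p<0.001)
#' applied to adjusted p-values. Pairs in which the weights are constant in
#' both groups are reported with `p = 1` and flagged.
#'
#' @param data Data frame with one row per cell/sample.
#' @param weight,group Columns (tidy-eval) holding the numeric weight and
#'   the group label.
#' @param test `"ranksum"` or `"ttest"`.
#' @return A tibble of class `group_comparison`: one row per pair with
#'   group sizes, means, medians, `statistic`, `p`, `p_adj`, `stars`,
#'   `degenerate`.
#' @export
compare_groups <- function(data, weight, group, test = c("ranksum", "ttest")) {
  test <- match.arg(test)
  w <- rlang::eval_tidy(rlang::enquo(weight), data)
  g <- as.character(rlang::eval_tidy(rlang::enquo(group), data))
  ok <- !is.na(w) & !is.na(g)
  w <- w[ok]; g <- g[ok]
  levels <- sort(unique(g))
  if (length(levels) < 2) stop("need at least 2 groups", call. = FALSE)
  counts <- table(g)
  if (any(counts < 2)) stop("each group needs n >= 2", call. = FALSE)
  pairs <- utils::combn(levels, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    x <- w[g == g1]; y <- w[g == g2]
    degenerate <- stats::sd(x) == 0 && stats::sd(y) == 0
    if (degenerate && test == "ranksum") {
      stat <- NA_real_
      p <- 1
    } else if (test == "ranksum") {
      ht <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
      stat <- unname(ht$statistic); p <- ht$p.value
    } else {
      if (degenerate) { stat <- NA_real_; p <- 1 } else {
        ht <- stats::t.test(x, y)
        stat <- unname(ht$statistic); p <- ht$p.value
      }
    }
    tibble::tibble(group1 = g1, group2 = g2,
                   n1 = length(x), n2 = length(y),
                   mean1 = mean(x), mean2 = mean(y),
                   median1 = stats::median(x), median2 = stats::median(y),
                   statistic = stat, p = p, degenerate = degenerate)
  })
  res <- dplyr::bind_rows(rows)
  res$p_adj <- bh_adjust(res$p)
  res$stars <- star_code(res$p_adj)
  class(res) <- c("group_comparison", class(res))
  res
}

#' ROC curve and AUC of a continuous weight against binary response
#'
#' AUC is the Mann-Whitney probability that a responder's weight exceeds a
#' non-responder's, with half credit for ties (computed from mid-ranks);
#' the curve is evaluated at every unique weight threshold.
#'
#' @param data Data frame with one row per sample.
#' @param weight,response Columns (tidy-eval): numeric weight and the
#'   response label.
#' @param positive Label counted as the positive class
#'   (default `"responder"`).
#' @return An object of class `roc_result`: list with `auc`, `curve`
#'   (tibble `threshold`, `tpr`, `fpr`), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(data, weight, response, positive = "responder") {
  w <- rlang::eval_tidy(rlang::enquo(weight), data)
  r <- rlang::eval_tidy(rlang::enquo(response), data)
  ok <- !is.na(w) & !is.na(r)
  w <- w[ok]
  pos <- r[ok] == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both response classes must be present", call. = FALSE)
  n1 <- as.numeric(n1); n0 <- as.numeric(n0)
  rk <- rank(w)                                   # mid-ranks: half credit for ties
  auc <- (sum(rk[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(w), decreasing = TRUE))
  curve <- tibble::tibble(
    threshold = thr,
    tpr = vapply(thr, function(t) mean(w[pos] >= t), numeric(1)),
    fpr = vapply(thr, function(t) mean(w[!pos] >= t), numeric(1))
  )
  structure(list(auc = auc, curve = curve, n_pos = n1, n_neg = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f (%d positives, %d negatives)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Multivariate Cox proportional hazards fit of pattern weights
#'
#' Age-adjusted (or arbitrary multivariate) Cox regression of overall
#' survival on pattern-weight covariates, fit by partial-likelihood
#' maximization with Breslow tie handling via [survival::coxph()]. Rows
#' with incomplete survival fields are excluded from this analysis only.
#' Wald tests per covariate; significance flagged at p < 0.05.
#'
#' @param clinical A [clinical_table()] (or data frame with `os_time`,
#'   `os_event` and the covariate columns).
#' @param covariates Character vector of covariate column names
#'   (e.g. `c("activation_weight", "age")`).
#' @param conf_level Confidence level of the hazard-ratio interval.
#' @return An object of class `cox_result`: tibble with one row per
#'   covariate (`term`, `coef`, `hr`, `se`, `p`, `conf_low`/`conf_high` on
#'   the coefficient (log-hazard) scale, `significant`) and attributes
#'   `n`, `n_events`, `converged`.
#' @export
cox_fit <- function(clinical, covariates, conf_level = 0.95) {
  tab <- tibble::as_tibble(clinical)
  miss <- setdiff(c("os_time", "os_event", covariates), names(tab))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  tab <- tab[stats::complete.cases(tab[, c("os_time", "os_event", covariates)]), ]
  if (sum(tab$os_event) < 2) stop("need at least 2 events", call. = FALSE)
  const <- covariates[vapply(covariates, function(v) stats::sd(tab[[v]]) == 0, logical(1))]
  if (length(const)) stop("constant covariate(s): ", paste(const, collapse = ", "), call. = FALSE)
  fml <- stats::as.formula(paste("survival::Surv(os_time, os_event) ~",
                                 paste(sprintf("`%s`", covariates), collapse = " + ")))
  fit <- survival::coxph(fml, data = tab, ties = "breslow")
  converged <- all(is.finite(stats::coef(fit))) && all(is.finite(diag(fit$var)))
  sm <- summary(fit, conf.int = conf_level)
  co <- sm$coefficients
  ci <- sm$conf.int
  res <- tibble::tibble(
    term = gsub("`", "", rownames(co)),
    coef = co[, "coef"],
    hr = exp(co[, "coef"]),
    se = co[, "se(coef)"],
    p = co[, "Pr(>|z|)"],
    conf_low = log(ci[, 3]), conf_high = log(ci[, 4]),   # coefficient scale
    significant = co[, "Pr(>|z|)"] < 0.05
  )
  attr(res, "n") <- sm$n
  attr(res, "n_events") <- sm$nevent
  attr(res, "converged") <- converged
  attr(res, "fit") <- fit
  class(res) <- c("cox_result", class(res))
  if (!converged) warning("Cox fit did not converge cleanly; inspect the result", call. = FALSE)
  res
}

#' Correlation with asymptotic test
#'
#' Spearman (tie-corrected ranks, asymptotic two-sided p) or Pearson
#' correlation via [stats::cor.test()].
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param method `"spearman"` or `"pearson"`.
#' @return A tibble with `rho`, `p`, `n`, `method`.
#' @export
correlate <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant vector", call. = FALSE)
  ht <- stats::cor.test(x, y, method = method, exact = FALSE)
  tibble::tibble(rho = unname(ht$estimate), p = ht$p.value,
                 n = length(x), method = method)
}

#' Correlate one gene's expression with external cell-type score columns
#'
#' Spearman correlation between a gene's expression and each numeric score
#' column (e.g. externally computed cell-type abundance estimates) over the
#' shared samples, BH-adjusted across columns with star coding.
#'
#' @param scores Data frame with `sample_id` plus numeric score columns.
#' @param gene_values Named numeric vector (names = sample ids), e.g. from
#'   [gene_values()].
#' @return A tibble with `cell_type`, `rho`, `p`, `p_adj`, `stars`, `n`.
#' @export
correlate_scores <- function(scores, gene_values) {
  scores <- tibble::as_tibble(scores)
  if (!"sample_id" %in% names(scores)) stop("scores need a sample_id column", call. = FALSE)
  shared <- intersect(scores$sample_id, names(gene_values))
  if (length(shared) == 0) stop("no shared samples between gene values and scores", call. = FALSE)
  sc <- scores[match(shared, scores$sample_id), , drop = FALSE]
  gv <- gene_values[shared]
  cols <- names(sc)[vapply(sc, is.numeric, logical(1))]
  rows <- lapply(cols, function(cn) {
    ct <- correlate(gv, sc[[cn]], method = "spearman")
    tibble::tibble(cell_type = cn, rho = ct$rho, p = ct$p, n = ct$n)
  })
  res <- dplyr::bind_rows(rows)
  # perfect correlations give asymptotic p = 0; clamp for the step-up
  res$p_adj <- bh_adjust(pmax(res$p, .Machine$double.xmin))
  res$stars <- star_code(res$p_adj)
  res
}

#' Extract one gene's expression as a named vector
#'
#' @param expr An [expression_matrix()].
#' @param gene Gene id.
#' @return Named numeric vector over samples.
#' @export
gene_values <- function(expr, gene) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (!gene %in% expr$gene_ids) stop("gene not present: ", gene, call. = FALSE)
  stats::setNames(expr$values[gene, ], expr$sample_ids)
}
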