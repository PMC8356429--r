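#' Build a validated pipeline configuration
#'
#' Collects every stage parameter with the module defaults; the seed has no
#' default and must be supplied explicitly — every stochastic stage derives
#' its own seed from it. The analysis thresholds (enrichment FDR < 0.05,
#' pseudotime q < 0.01, Cox p < 0.05) are named keys.
#'
#' @param seed Integer master seed (required).
#' @param n_genes,n_cells,K,n_cell_types,sparsity Synthetic-truth settings.
#' @param n_patterns Patterns requested from the factorization.
#' @param n_sets Consensus subsets.
#' @param n_iterations Maximum alternating sweeps per subset fit.
#' @param sparsity_penalty L1 penalty of the factorization.
#' @param match_threshold,min_subset_fraction Consensus clustering controls.
#' @param homolog_dropout Fraction of genes absent from the homolog table.
#' @param n_patients Patients in the simulated clinical table.
#' @param n_perm Enrichment permutations.
#' @param enrichment_fdr,pseudotime_q,cox_p Significance thresholds.
#' @param k_neighbors Pseudotime graph neighbors.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed,
                            n_genes = 200, n_cells = 300, K = 4,
                            n_cell_types = 3, sparsity = 0.8,
                            n_patterns = 4, n_sets = 3,
                            n_iterations = 2000, sparsity_penalty = 0,
                            match_threshold = 0.7, min_subset_fraction = 0.5,
                            homolog_dropout = 0.3, n_patients = 500,
                            n_perm = 1000, enrichment_fdr = 0.05,
                            pseudotime_q = 0.01, cox_p = 0.05,
                            k_neighbors = 15) {
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stop("pipeline_config requires an explicit integer seed", call. = FALSE)
  }
  cfg <- list(seed = as.integer(seed), n_genes = n_genes, n_cells = n_cells,
              K = K, n_cell_types = n_cell_types, sparsity = sparsity,
              n_patterns = n_patterns, n_sets = n_sets,
              n_iterations = n_iterations, sparsity_penalty = sparsity_penalty,
              match_threshold = match_threshold,
              min_subset_fraction = min_subset_fraction,
              homolog_dropout = homolog_dropout, n_patients = n_patients,
              n_perm = n_perm, enrichment_fdr = enrichment_fdr,
              pseudotime_q = pseudotime_q, cox_p = cox_p,
              k_neighbors = k_neighbors)
  class(cfg) <- "pipeline_config"
  cfg
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

#' Run the full synthetic workflow end to end
#'
#' Executes simulate -> preprocess/factorize -> markers/enrichment ->
#' cross-species projection -> clinical association -> pseudotime in
#' dependency order, writing each stage's artifacts (TSV matrices, JSON
#' summaries) plus a provenance record to `out_dir`. Re-running with the
#' same configuration reproduces byte-identical TSV outputs. A stage
#' failure aborts with the failing stage named; artifacts written up to
#' that point are moved to a `failed/` subdirectory.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and
#'   `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "pipeline_config")) {
    stop("config must be built with pipeline_config() (explicit seed required)",
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  current_stage <- "setup"
  fail <- function(e) {
    dest <- file.path(out_dir, "failed")
    dir.create(dest, showWarnings = FALSE)
    arts <- setdiff(list.files(out_dir, full.names = TRUE), dest)
    file.copy(arts, dest, recursive = TRUE)
    unlink(arts, recursive = TRUE)
    stop("pipeline stage '", current_stage, "' failed: ",
         conditionMessage(e), call. = FALSE)
  }
  res <- tryCatch({
    write_json_file(unclass(config), file.path(out_dir, "config.json"))

    current_stage <- "simulate"
    truth <- simulate_truth(n_genes = config$n_genes, n_cells = config$n_cells,
                            K = config$K, n_cell_types = config$n_cell_types,
                            sparsity = config$sparsity, seed = config$seed)
    expr <- simulate_expression(truth)
    target <- simulate_target_species(truth,
                                      homolog_dropout = config$homolog_dropout)
    clinical <- simulate_clinical(truth, n_patients = config$n_patients)
    write_json_file(list(k_star = truth$k_star, noise_sd = truth$noise_sd,
                         sparsity = truth$sparsity,
                         activation_shift = truth$activation_shift,
                         response_model = truth$response_model,
                         survival_model = truth$survival_model,
                         seed = truth$seed),
                    file.path(out_dir, "truth.json"))
    readr::write_tsv(tibble::as_tibble(clinical), file.path(out_dir, "clinical.tsv"))

    current_stage <- "factorize"
    pre <- preprocess(expr)
    fit <- consensus_factorize(pre, n_patterns = config$n_patterns,
                               n_sets = config$n_sets,
                               n_iterations = config$n_iterations,
                               sparsity_penalty = config$sparsity_penalty,
                               match_threshold = config$match_threshold,
                               min_subset_fraction = config$min_subset_fraction,
                               seed = config$seed + 100)
    write_matrix_tsv(fit$A, file.path(out_dir, "A.tsv"), id_col = "gene_id")
    write_matrix_tsv(t(fit$P), file.path(out_dir, "P.tsv"), id_col = "sample_id")
    # fitted pattern best matching the planted activation program
    cors <- stats::cor(fit$A[rownames(truth$A_true), , drop = FALSE],
                       truth$A_true[, truth$k_star])
    k_star_est <- rownames(cors)[which.max(cors)]

    current_stage <- "markers"
    mk <- pattern_markers(fit$A)
    readr::write_tsv(tibble::as_tibble(mk), file.path(out_dir, "markers.tsv"))

    current_stage <- "enrich"
    sets <- truth_program_sets(truth)
    write_gmt(sets, file.path(out_dir, "gene_sets.gmt"))
    enr <- geneset_enrichment(fit$A, sets, n_perm = config$n_perm,
                              seed = config$seed + 200)
    readr::write_tsv(tibble::as_tibble(enr), file.path(out_dir, "enrichment.tsv"))

    current_stage <- "project"
    proj <- project(fit$A, target$expr, homologs = target$homolog_map,
                    mode = "ols", center_genes = FALSE)
    write_matrix_tsv(t(proj$P_new), file.path(out_dir, "projection.tsv"),
                     id_col = "sample_id")

    current_stage <- "associate"
    pw <- tidy(proj)
    target_type <- unique(target$expr$sample_meta$cell_type)[1]
    nk <- pw[pw$pattern == k_star_est & pw$cell_type == target_type, , drop = FALSE]
    cmp <- compare_groups(nk, weight, treatment)
    roc <- roc_auc(clinical, activation_weight, response)
    cox <- cox_fit(clinical, covariates = c("activation_weight", "age"))
    write_json_file(list(
      k_star_estimated = k_star_est,
      group_comparison = cmp,
      roc_auc = glance(roc)$auc,
      cox = tidy(cox)
    ), file.path(out_dir, "associations.json"))

    current_stage <- "trajectory"
    nk_ids <- expr$sample_meta$sample_id[expr$sample_meta$cell_type == target_type]
    nk_expr <- subset_expression(expr, samples = nk_ids)
    wts <- stats::setNames(fit$P[k_star_est, nk_ids], nk_ids)
    ptime <- order_cells_pseudotime(nk_expr, wts,
                                    k_neighbors = config$k_neighbors)
    assoc <- pseudotime_gene_association(nk_expr, ptime,
                                         q_cutoff = config$pseudotime_q)
    inter <- intersect_with_markers(assoc$gene_id[assoc$selected],
                                    markers_for(mk, k_star_est))
    readr::write_tsv(tibble::as_tibble(ptime), file.path(out_dir, "pseudotime.tsv"))
    readr::write_tsv(assoc, file.path(out_dir, "pseudotime_genes.tsv"))

    current_stage <- "provenance"
    write_json_file(list(
      seed = config$seed, K_final = fit$K_final,
      k_star_estimated = k_star_est,
      genes_used = proj$genes_used, genes_dropped = proj$genes_dropped,
      n_iterations = fit$n_iterations,
      n_pseudotime_genes = sum(assoc$selected),
      n_marker_intersection = length(inter),
      thresholds = list(enrichment_fdr = config$enrichment_fdr,
                        pseudotime_q = config$pseudotime_q,
                        cox_p = config$cox_p),
      pseudotime_note = paste("pseudotime = kNN-graph geodesic from a",
                              "low-weight root; gene association = Spearman")
    ), file.path(out_dir, "provenance.json"))

    list(truth = truth, expr = expr, fit = fit, markers = mk,
         enrichment = enr, projection = proj, comparison = cmp, roc = roc,
         cox = cox, pseudotime = ptime, pseudotime_genes = assoc,
         marker_intersection = inter, k_star_estimated = k_star_est,
         out_dir = out_dir)
  }, error = fail)
  invisible(res)
}

#' Gene sets derived from the planted programs' top-decile loadings
#'
#' One set per planted pattern, containing the genes in the top decile of
#' that pattern's true loadings — the positive-control collection for the
#' enrichment stage.
#'
#' @param truth A [simulate_truth()] object.
#' @param top_fraction Fraction of genes per set (default 0.1).
#' @return A `geneset_collection`.
#' @export
truth_program_sets <- function(truth, top_fraction = 0.1) {
  A <- truth$A_true
  n_top <- max(3, round(top_fraction * nrow(A)))
  sets <- lapply(seq_len(ncol(A)), function(k) {
    rownames(A)[order(-A[, k])][seq_len(n_top)]
  })
  names(sets) <- paste0("program_", seq_len(ncol(A)))
  geneset_collection(sets)
}
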