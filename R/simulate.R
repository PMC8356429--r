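#' Simulate planted ground truth for the cross-species pipeline
#'
#' Generates the latent structure the whole pipeline is validated against:
#' a non-negative gene-loading matrix `A_true` with controlled sparsity, a
#' non-negative cell-weight matrix `P_true` with cell-type block structure,
#' and a designated activation pattern `k_star` that is non-zero only within
#' one target cell type and further elevated in treated cells of that type —
#' the structure of a treatment-induced activation program confined to NK
#' cells. Response and survival generative models tied to the activation
#' weight are attached so clinical stages can be tested against known
#' parameters.
#'
#' @param n_genes,n_cells Dimensions of the simulated expression data.
#' @param K Number of latent patterns; must be at least `n_cell_types + 1`
#'   (one identity pattern per cell type plus at least one state pattern).
#' @param n_cell_types Number of cell types; the first (`"NK"`) carries the
#'   activation program.
#' @param sparsity Fraction of zero entries targeted in each `A_true` column
#'   (must be < 1).
#' @param activation_shift Additive mean shift of the activation weight in
#'   treated cells of the target type, in pattern-weight units.
#' @param noise_sd Gaussian noise s.d. on the log2 scale; the default
#'   (`NULL`) is calibrated to 10% of the s.d. of the noiseless signal.
#' @param auc_target Generative AUC linking the (standardized) activation
#'   weight to binary response in [simulate_clinical()].
#' @param beta_activation,beta_age Proportional-hazards log-hazard
#'   coefficients of the survival generative model.
#' @param seed Integer seed; all outputs are deterministic given it.
#'
#' @return An object of class `synthetic_truth`: list with `A_true`
#'   (genes x K, columns scaled to unit maximum), `P_true` (K x cells),
#'   `k_star`, `cell_type_labels`, `treatment_labels`, `noise_sd`,
#'   `response_model`, `survival_model`, `sparsity`, `activation_shift`,
#'   `seed`.
#' @export
simulate_truth <- function(n_genes = 200, n_cells = 300, K = 4,
                           n_cell_types = 3, sparsity = 0.8,
                           activation_shift = 1, noise_sd = NULL,
                           auc_target = 0.75,
                           beta_activation = -0.5, beta_age = 0.02,
                           seed = 1) {
  if (K < n_cell_types + 1) {
    stop("K must be at least n_cell_types + 1 (identity patterns plus a state pattern)",
         call. = FALSE)
  }
  if (sparsity >= 1 || sparsity < 0) {
    stop("sparsity must be in [0, 1); all-zero loadings are infeasible", call. = FALSE)
  }
  if (n_genes < 2 * K || n_cells < 2 * K) stop("infeasible dimensions", call. = FALSE)
  rng <- local_seed(seed)

  gene_ids <- sprintf("Gene%04d", seq_len(n_genes))
  type_names <- c("NK", "T_cell", "Macrophage", "B_cell", "DC", "Monocyte",
                  "Neutrophil", "pDC")
  if (n_cell_types > length(type_names)) {
    type_names <- c(type_names, sprintf("type%02d", seq_len(n_cell_types)))
  }
  types <- type_names[seq_len(n_cell_types)]
  k_star <- K

  # loadings: each column sparse non-negative, gamma-distributed amplitudes
  A <- matrix(0, n_genes, K, dimnames = list(gene_ids, paste0("pattern_", seq_len(K))))
  for (k in seq_len(K)) {
    n_on <- max(K, round((1 - sparsity) * n_genes))
    on <- sample.int(n_genes, n_on)
    A[on, k] <- stats::rgamma(n_on, shape = 2, rate = 2)
  }
  # guard: no all-zero column, scale to unit maximum
  for (k in seq_len(K)) {
    if (max(A[, k]) <= 0) A[sample.int(n_genes, K), k] <- 1
    A[, k] <- A[, k] / max(A[, k])
  }

  cell_types <- rep(types, length.out = n_cells)
  treatment <- rep(c("control", "anti-CTLA-4"), length.out = n_cells)
  cell_ids <- sprintf("cell_%04d", seq_len(n_cells))

  P <- matrix(0, K, n_cells, dimnames = list(colnames(A), cell_ids))
  # every cell uses a little of every non-activation program (background
  # usage ~ 0.1); its own identity program dominates (~ 1)
  for (k in setdiff(seq_len(K), k_star)) {
    P[k, ] <- stats::rgamma(n_cells, shape = 1, rate = 10)
  }
  for (j in seq_len(n_cells)) {
    t_idx <- match(cell_types[j], types)
    P[t_idx, j] <- stats::rgamma(1, shape = 10, rate = 10)
  }
  target <- cell_types == types[1]
  treated <- treatment == "anti-CTLA-4"
  n_t <- sum(target)
  base_w <- stats::rgamma(n_t, shape = 4, rate = 8)           # resting usage ~ 0.5
  P[k_star, target] <- base_w
  P[k_star, target & treated] <- P[k_star, target & treated] +
    activation_shift * (0.75 + 0.5 * stats::runif(sum(target & treated)))

  signal <- A %*% P
  if (is.null(noise_sd)) noise_sd <- 0.1 * stats::sd(signal)

  b0 <- 0
  b1 <- calibrate_logistic_slope(auc_target, intercept = b0)

  structure(list(
    A_true = A, P_true = P, k_star = k_star,
    cell_type_labels = stats::setNames(cell_types, cell_ids),
    treatment_labels = stats::setNames(treatment, cell_ids),
    noise_sd = noise_sd, sparsity = sparsity,
    activation_shift = activation_shift,
    response_model = list(intercept = b0, slope = b1, auc_target = auc_target),
    survival_model = list(beta_activation = beta_activation, beta_age = beta_age,
                          baseline_hazard = 1 / 1000),
    seed = seed
  ), class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d genes, %d cells, K=%d (activation pattern %d in %s)\n",
              nrow(x$A_true), ncol(x$P_true), ncol(x$A_true), x$k_star,
              x$cell_type_labels[[1]]))
  invisible(x)
}

#' Simulate a log2 expression matrix from planted truth
#'
#' Values are `pmax(A_true %*% P_true + N(0, noise_sd), 0)` on the log2
#' scale (the scale factorization operates on). A count-mode
#' (`Poisson(2^x - 1)`) is available for realism.
#'
#' @param truth A [simulate_truth()] object.
#' @param noise_sd Override of the truth's noise level.
#' @param mode `"log2"` (truncated-Gaussian noise on the product) or
#'   `"counts"` (Poisson counts of the back-transformed product).
#' @param seed Seed for the noise draw; defaults to `truth$seed + 1`.
#' @return An [expression_matrix()] whose `sample_meta` carries `cell_type`,
#'   `treatment` and the planted activation weight
#'   (`true_activation_weight`).
#' @export
simulate_expression <- function(truth, noise_sd = truth$noise_sd,
                                mode = c("log2", "counts"),
                                seed = truth$seed + 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  mode <- match.arg(mode)
  rng <- local_seed(seed)
  signal <- truth$A_true %*% truth$P_true
  if (mode == "log2") {
    vals <- pmax(signal + stats::rnorm(length(signal), 0, noise_sd), 0)
    space <- "log2"
  } else {
    vals <- matrix(stats::rpois(length(signal), lambda = 2^signal - 1),
                   nrow(signal), ncol(signal))
    space <- "counts"
  }
  dim(vals) <- dim(signal)
  meta <- tibble::tibble(
    sample_id = colnames(truth$P_true),
    cell_type = unname(truth$cell_type_labels),
    treatment = unname(truth$treatment_labels),
    true_activation_weight = truth$P_true[truth$k_star, ]
  )
  expression_matrix(vals, gene_ids = rownames(truth$A_true),
                    sample_ids = colnames(truth$P_true),
                    sample_meta = meta, space = space)
}

# draw a fresh P with the truth's block/treatment structure (shared by the
# target-species and panel simulators)
draw_weights <- function(truth, n_cells, prefix = "tcell") {
  K <- ncol(truth$A_true)
  n_types <- length(unique(truth$cell_type_labels))
  types <- unique(unname(truth$cell_type_labels))
  k_star <- truth$k_star
  cell_types <- rep(types, length.out = n_cells)
  treatment <- rep(c("control", "anti-CTLA-4"), length.out = n_cells)
  ids <- sprintf("%s_%04d", prefix, seq_len(n_cells))
  P <- matrix(0, K, n_cells, dimnames = list(colnames(truth$A_true), ids))
  for (k in setdiff(seq_len(K), k_star)) {
    P[k, ] <- stats::rgamma(n_cells, shape = 1, rate = 10)
  }
  for (j in seq_len(n_cells)) {
    t_idx <- match(cell_types[j], types)
    P[t_idx, j] <- stats::rgamma(1, shape = 10, rate = 10)
  }
  target <- cell_types == types[1]
  treated <- treatment == "anti-CTLA-4"
  P[k_star, target] <- stats::rgamma(sum(target), shape = 4, rate = 8)
  P[k_star, target & treated] <- P[k_star, target & treated] +
    truth$activation_shift * (0.75 + 0.5 * stats::runif(sum(target & treated)))
  list(P = P, cell_types = cell_types, treatment = treatment, ids = ids)
}

#' Simulate a target-species dataset with a partial homolog table
#'
#' New cells are drawn from the same planted loadings, gene symbols are
#' renamed to target-species convention (`Gene0007` -> `GENE0007`), and a
#' fraction of genes is omitted from the homolog table, emulating
#' cross-species projection where genes without homologs are removed. The
#' target expression itself covers the full gene set.
#'
#' @param truth A [simulate_truth()] object.
#' @param n_cells Number of target-species cells.
#' @param homolog_dropout Fraction of genes missing from the homolog table,
#'   in [0, 1).
#' @param noise_sd Noise level; defaults to the truth's.
#' @param seed Seed.
#' @return List with `expr` (target [expression_matrix()]), `homolog_map`
#'   (source -> target, one-to-one), `P_true` (planted weights of the target
#'   cells).
#' @export
simulate_target_species <- function(truth, n_cells = 300, homolog_dropout = 0.3,
                                    noise_sd = truth$noise_sd,
                                    seed = truth$seed + 2) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (homolog_dropout < 0 || homolog_dropout >= 1) {
    stop("homolog_dropout must be in [0, 1)", call. = FALSE)
  }
  rng <- local_seed(seed)
  dw <- draw_weights(truth, n_cells, prefix = "hcell")
  src_genes <- rownames(truth$A_true)
  tgt_genes <- toupper(src_genes)
  signal <- truth$A_true %*% dw$P
  vals <- pmax(signal + stats::rnorm(length(signal), 0, noise_sd), 0)
  meta <- tibble::tibble(sample_id = dw$ids, cell_type = dw$cell_types,
                         treatment = dw$treatment,
                         true_activation_weight = dw$P[truth$k_star, ])
  expr <- expression_matrix(vals, gene_ids = tgt_genes, sample_ids = dw$ids,
                            sample_meta = meta, space = "log2")
  n_keep <- round((1 - homolog_dropout) * length(src_genes))
  if (n_keep < ncol(truth$A_true)) {
    stop("homolog dropout leaves fewer mapped genes than patterns", call. = FALSE)
  }
  keep <- sort(sample.int(length(src_genes), n_keep))
  hmap <- homolog_map(tibble::tibble(source_gene = src_genes[keep],
                                     target_gene = tgt_genes[keep]))
  list(expr = expr, homolog_map = hmap, P_true = dw$P)
}

#' Simulate a reduced marker-like feature panel (CyTOF analog)
#'
#' Selects `n_features` genes with sampling probability proportional to the
#' squared row-maximum loading (marker-like panel biased toward
#' pattern-specific genes) and emits a panel-only expression matrix for new
#' cells drawn from the planted model.
#'
#' @param truth A [simulate_truth()] object.
#' @param n_features Panel size; must be at least the number of patterns.
#' @param n_cells Number of panel cells.
#' @param noise_sd Noise level; defaults to the truth's.
#' @param seed Seed.
#' @return List with `expr` (panel [expression_matrix()]), `features`, and
#'   `P_true` (planted weights of the panel cells).
#' @export
simulate_feature_panel <- function(truth, n_features = 30, n_cells = 300,
                                   noise_sd = truth$noise_sd,
                                   seed = truth$seed + 3) {
  stopifnot(inherits(truth, "synthetic_truth"))
  K <- ncol(truth$A_true)
  if (n_features < K) stop("n_features must be at least the number of patterns", call. = FALSE)
  rng <- local_seed(seed)
  rmax <- apply(truth$A_true, 1, max)
  prob <- rmax^2 + 1e-9
  feats <- sort(sample.int(nrow(truth$A_true), n_features, prob = prob))
  dw <- draw_weights(truth, n_cells, prefix = "pcell")
  signal <- truth$A_true[feats, , drop = FALSE] %*% dw$P
  vals <- pmax(signal + stats::rnorm(length(signal), 0, noise_sd), 0)
  meta <- tibble::tibble(sample_id = dw$ids, cell_type = dw$cell_types,
                         treatment = dw$treatment,
                         true_activation_weight = dw$P[truth$k_star, ])
  expr <- expression_matrix(vals, gene_ids = rownames(truth$A_true)[feats],
                            sample_ids = dw$ids, sample_meta = meta,
                            space = "log2")
  list(expr = expr, features = rownames(truth$A_true)[feats], P_true = dw$P)
}

#' Simulate a per-patient clinical table linked to the activation weight
#'
#' Each patient carries a standardized mean activation weight `w ~ N(0, 1)`.
#' Binary response follows a logistic model whose slope is calibrated (by
#' deterministic quadrature of the logistic-normal AUC integral) so the
#' generative AUC of `w` equals `auc_target`; slope 0 gives the null.
#' Survival times are exponential proportional hazards in `w` and age, with
#' independent uniform censoring tuned to the requested censoring rate.
#'
#' @param truth A [simulate_truth()] object (provides the generative
#'   coefficients).
#' @param n_patients Number of patients.
#' @param censor_rate Target fraction censored (default 0.3).
#' @param auc_target Override of the truth's generative AUC; `NULL` keeps it.
#'   Set `slope = 0` via `auc_target = 0.5` for the null model.
#' @param seed Seed.
#' @return A [clinical_table()] tibble with columns `sample_id`, `os_time`,
#'   `os_event`, `age`, `response`, `treatment`, and the planted
#'   `activation_weight`.
#' @export
simulate_clinical <- function(truth, n_patients = 500, censor_rate = 0.3,
                              auc_target = NULL, seed = truth$seed + 4) {
  stopifnot(inherits(truth, "synthetic_truth"))
  rng <- local_seed(seed)
  b0 <- truth$response_model$intercept
  b1 <- if (is.null(auc_target)) truth$response_model$slope else
    calibrate_logistic_slope(auc_target, intercept = b0)
  w <- stats::rnorm(n_patients)
  response <- ifelse(stats::runif(n_patients) < stats::plogis(b0 + b1 * w),
                     "responder", "non-responder")
  age <- stats::rnorm(n_patients, 60, 10)
  sm <- truth$survival_model
  rate <- sm$baseline_hazard *
    exp(sm$beta_activation * w + sm$beta_age * (age - 60))
  t_event <- stats::rexp(n_patients, rate = rate)
  cmax <- censor_horizon(rate, censor_rate)
  t_cens <- stats::runif(n_patients, 0, cmax)
  os_time <- pmin(t_event, t_cens)
  os_event <- as.integer(t_event <= t_cens)
  clinical_table(tibble::tibble(
    sample_id = sprintf("patient_%04d", seq_len(n_patients)),
    os_time = os_time, os_event = os_event, age = age,
    response = response, treatment = "anti-CTLA-4",
    activation_weight = w
  ))
}

#' Simulate per-patient bulk expression tied to a clinical table
#'
#' Builds one bulk profile per patient as a mixture of the planted
#' programs: cell-type identity usages drawn around equal proportions, and
#' the activation program's usage a monotone increasing transform of the
#' patient's standardized activation weight from [simulate_clinical()]
#' (so classification performance carries over: AUC is invariant to
#' monotone transforms). Used to test response classification from
#' projected bulk weights.
#'
#' @param truth A [simulate_truth()] object.
#' @param clinical A [simulate_clinical()] table for the same truth.
#' @param noise_sd Noise level; defaults to the truth's.
#' @param seed Seed.
#' @return An [expression_matrix()] (genes x patients) whose `sample_meta`
#'   carries the clinical columns and the bulk activation usage
#'   (`true_activation_weight`).
#' @export
simulate_patient_bulk <- function(truth, clinical, noise_sd = truth$noise_sd,
                                  seed = truth$seed + 5) {
  stopifnot(inherits(truth, "synthetic_truth"))
  rng <- local_seed(seed)
  n <- nrow(clinical)
  K <- ncol(truth$A_true)
  n_types <- length(unique(truth$cell_type_labels))
  P <- matrix(0, K, n, dimnames = list(colnames(truth$A_true),
                                       clinical$sample_id))
  for (k in seq_len(n_types)) {
    P[k, ] <- stats::rgamma(n, shape = 8, rate = 8) / n_types
  }
  extra <- setdiff(seq_len(K), c(seq_len(n_types), truth$k_star))
  for (k in extra) P[k, ] <- stats::rgamma(n, shape = 2, rate = 10)
  # monotone link from the standardized patient weight to bulk usage
  P[truth$k_star, ] <- pmax(0.4 + 0.15 * clinical$activation_weight, 0.01)
  vals <- pmax(truth$A_true %*% P +
                 stats::rnorm(nrow(truth$A_true) * n, 0, noise_sd), 0)
  meta <- dplyr::bind_cols(
    tibble::as_tibble(clinical)[, c("sample_id", "response", "treatment",
                                    "os_time", "os_event", "age")],
    tibble::tibble(true_activation_weight = P[truth$k_star, ])
  )
  expression_matrix(vals, gene_ids = rownames(truth$A_true),
                    sample_ids = clinical$sample_id, sample_meta = meta,
                    space = "log2")
}

# horizon of Uniform(0, cmax) censoring achieving the requested censoring
# probability for exponential event times with the given subject rates
censor_horizon <- function(rates, censor_rate) {
  if (censor_rate <= 0) return(Inf)
  p_cens <- function(cmax) {
    mean((1 - exp(-rates * cmax)) / (rates * cmax)) - censor_rate
  }
  # p_cens decreases from 1 (cmax -> 0) to 0 (cmax -> Inf)
  lo <- 1e-6 / mean(rates); hi <- 1e6 / mean(rates)
  stats::uniroot(p_cens, c(lo, hi), tol = 1e-8)$root
}

#' Calibrate the logistic slope for a target generative AUC
#'
#' For a standard-normal score `w` and response probability
#' `plogis(intercept + slope * w)`, the population AUC of `w` as a classifier
#' is a smooth increasing function of the slope. This computes it by
#' two-dimensional Gauss-Legendre quadrature and inverts it with
#' [stats::uniroot()]. Used both by the generator and as the closed-form
#' oracle in tests.
#'
#' @param auc_target Desired AUC in [0.5, 1).
#' @param intercept Logistic intercept.
#' @return The slope (0 when `auc_target` is 0.5).
#' @export
calibrate_logistic_slope <- function(auc_target, intercept = 0) {
  if (auc_target < 0.5 || auc_target >= 1) {
    stop("auc_target must be in [0.5, 1)", call. = FALSE)
  }
  if (abs(auc_target - 0.5) < 1e-12) return(0)
  f <- function(b1) logistic_normal_auc(b1, intercept) - auc_target
  stats::uniroot(f, c(1e-6, 100), tol = 1e-10)$root
}

#' Population AUC of a standard-normal score under a logistic response model
#'
#' @param slope,intercept Logistic coefficients.
#' @param n_nodes Quadrature nodes per dimension.
#' @return The AUC (probability a responder's score exceeds a
#'   non-responder's).
#' @export
logistic_normal_auc <- function(slope, intercept = 0, n_nodes = 256) {
  if (slope == 0) return(0.5)
  # Gauss-Legendre on [-10, 10] against the normal density
  gl <- pracma::gaussLegendre(n_nodes, -10, 10)
  u <- gl$x; wts <- gl$w * stats::dnorm(u)
  p <- stats::plogis(intercept + slope * u)
  p1 <- sum(wts * p)                       # P(responder)
  # P(W_resp > W_nonresp) = E[ p(u) (1-p(v)) 1{u > v} ] / (p1 (1 - p1))
  outer_mass <- outer(wts * p, wts * (1 - p))     # u rows, v cols
  ind <- outer(u, u, ">")
  num <- sum(outer_mass * ind) + 0.5 * sum(diag(outer_mass))
  num / (p1 * (1 - p1))
}

local_seed <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  set.seed(as.integer(seed))
  invisible(seed)
}
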