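# End-to-end fitting and candidate ranking.
#
# fit_mksvm() builds both kernels from windows + profiles, combines
# them and trains the SVM, keeping on the model everything needed to
# score new sites out of sample: the support windows and profiles, the
# sequence-kernel normalisation constants and the kernel configuration.

#' Fit the multiple-kernel SVM on a full labeled dataset
#'
#' Computes the raw BLOSUM62 similarity over all training windows,
#' min-max normalises it, computes the GIP kernel from the profile
#' matrix, combines both with the configured weights and trains the
#' SVM. No masking is applied here — this is the final model trained on
#' all labeled data; masking only happens inside cross-validation and
#' when scoring unlabeled candidates.
#'
#' @param windows Named character vector of peptide windows.
#' @param profiles Binary site x PTM matrix aligned with `windows`.
#' @param data A [labeled_dataset()] aligned with `windows`.
#' @param config A [kernel_config()].
#' @param params A [model_params()].
#' @return A `ptm_svm` carrying `support_windows`, `support_profiles`,
#'   `norm_constants`, `config` and `target_ptm`.
#' @export
fit_mksvm <- function(windows, profiles, data, config = kernel_config(),
                      params = model_params()) {
  if (!identical(names(windows), data$site_ids) ||
      !identical(rownames(profiles), data$site_ids)) {
    stop_validation("windows, profiles and dataset must share site ids ",
                    "in the same order")
  }
  S <- seq_similarity_matrix(windows)
  nm <- minmax_normalize(S)
  G <- gip_kernel(profiles, config$gamma)
  K <- combine_kernels(list(nm$K, G), config$betas)
  if (isTRUE(config$psd_repair)) K <- nearest_psd(K)
  model <- train_mksvm(K, data$labels, params)
  model$norm_constants <- c(nm$min_val, nm$max_val)
  model$config <- config
  model$target_ptm <- data$target_ptm
  model$support_windows <- windows[model$support_index]
  model$support_profiles <- profiles[model$support_index, , drop = FALSE]
  model
}

#' Select kernel weights by cross-validated AUC
#'
#' Scans `beta_seq` over a grid (with `beta_gip = 1 - beta_seq`), runs
#' cross-validation at each point and returns the grid with its AUCs
#' and the best weight pair. The default weights (0.5, 0.5) are an
#' uninformative prior; this helper is the optional data-driven
#' alternative.
#'
#' @inheritParams run_cv
#' @param grid Values of the sequence-kernel weight to try.
#' @param folds,repeats,seed Cross-validation settings for the search.
#' @param gamma GIP bandwidth.
#' @return A list with `table` (data.frame `beta_seq`, `beta_gip`,
#'   `auc`) and `best` (named beta vector).
#' @export
tune_betas <- function(windows, profiles, data, grid = seq(0, 1, 0.1),
                       folds = 5L, repeats = 1L, seed = 1L,
                       gamma = 0.001, params = model_params()) {
  auc <- vapply(grid, function(b1) {
    cfg <- kernel_config(gamma = gamma, betas = c(seq = b1, gip = 1 - b1))
    run_cv(windows, profiles, data, cfg, params, folds = folds,
           repeats = repeats, seed = seed)$average$AUC
  }, numeric(1))
  best <- grid[which.max(auc)]
  list(table = data.frame(beta_seq = grid, beta_gip = 1 - grid, auc = auc),
       best = c(seq = best, gip = 1 - best))
}

# Rectangular raw BLOSUM62 similarity block between two window sets.
seq_cross_similarity <- function(windows_a, windows_b) {
  ea <- encode_windows(windows_a)
  eb <- encode_windows(windows_b)
  if (ncol(ea) != ncol(eb)) stop_validation("window lengths differ")
  B <- blosum62_matrix()
  S <- matrix(0, nrow(ea), nrow(eb),
              dimnames = list(rownames(ea), rownames(eb)))
  for (x in seq_len(ncol(ea))) {
    S <- S + B[ea[, x], eb[, x]]
  }
  S
}

# Rectangular GIP block between two binary profile sets (shared columns).
gip_cross <- function(A_query, A_ref, gamma) {
  if (!identical(colnames(A_query), colnames(A_ref))) {
    stop_validation("profile matrices disagree on PTM columns")
  }
  Aq <- matrix(as.numeric(A_query), nrow(A_query), ncol(A_query))
  Ar <- matrix(as.numeric(A_ref), nrow(A_ref), ncol(A_ref))
  d2 <- outer(rowSums(Aq), rowSums(Ar), "+") - 2 * tcrossprod(Aq, Ar)
  d2[d2 < 0] <- 0
  K <- exp(-gamma * d2)
  dimnames(K) <- list(rownames(A_query), rownames(A_ref))
  K
}

# Combined kernel block between candidate sites and the model's support
# set; the candidates' target-PTM column is treated as 0 (their status
# for the target modification is exactly what is being predicted).
candidate_kernel_block <- function(model, candidate_windows,
                                   candidate_profiles) {
  if (is.null(model$support_windows) || is.null(model$support_profiles)) {
    stop_validation("model does not carry support windows/profiles; ",
                    "fit it with fit_mksvm()")
  }
  S_cross <- seq_cross_similarity(candidate_windows, model$support_windows)
  Kseq <- apply_normalization(S_cross, model$norm_constants[1L],
                              model$norm_constants[2L])
  A <- candidate_profiles[, colnames(model$support_profiles), drop = FALSE]
  if (model$target_ptm %in% colnames(A)) {
    A[, model$target_ptm] <- 0L
  }
  Kgip <- gip_cross(A, model$support_profiles, model$config$gamma)
  b <- model$config$betas
  b[[1L]] * Kseq + b[[2L]] * Kgip
}

#' Rank unlabeled candidate sites by predicted probability
#'
#' Scores each candidate against the model's support sites through the
#' combined kernel (with the candidates' target-PTM annotation treated
#' as absent), converts decision values to probabilities via the
#' model's Platt map and returns the candidates sorted by decreasing
#' probability, ties broken by site id.
#'
#' @param model A `ptm_svm` from [fit_mksvm()] trained with
#'   `probability = TRUE`.
#' @param candidate_windows Named character vector of candidate windows.
#' @param candidate_profiles Binary profile matrix for the candidates
#'   (same PTM columns as the training profiles).
#' @return A data.frame with `rank`, `site_id`, `probability`, `score`.
#' @export
rank_candidates <- function(model, candidate_windows, candidate_profiles) {
  if (length(candidate_windows) == 0L) {
    return(data.frame(rank = integer(), site_id = character(),
                      probability = numeric(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  K <- candidate_kernel_block(model, candidate_windows, candidate_profiles)
  scores <- decision_values(model, K)
  prob <- predict_proba(model, scores)
  ids <- names(candidate_windows)
  ord <- order(-prob, ids)
  data.frame(rank = seq_along(ord), site_id = ids[ord],
             probability = prob[ord], score = scores[ord],
             row.names = NULL, stringsAsFactors = FALSE)
}
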