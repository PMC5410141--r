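# Performance assessment.
#
# The evaluation protocol is stratified ten-fold cross-validation
# repeated ten times. Within each fold the interaction-profile kernel is
# recomputed from a masked adjacency matrix (the target-PTM annotations
# of held-out sites are removed), and the sequence-kernel normalisation
# constants are taken from the training block only, so no information
# about held-out labels can reach training. Metrics are computed on the
# scores pooled within each repeat and then averaged across repeats.

#' Labeled prediction task
#'
#' @param site_ids Character vector of site identifiers.
#' @param labels Numeric +1/-1 task labels, aligned with `site_ids`.
#' @param target_ptm Name of the PTM or kinase group under prediction;
#'   must match a column of the interaction-profile matrix.
#' @return A list of class `ptm_dataset`.
#' @export
labeled_dataset <- function(site_ids, labels, target_ptm) {
  if (length(site_ids) != length(labels)) {
    stop_validation("site_ids and labels differ in length")
  }
  if (!all(labels %in% c(-1, 1))) {
    stop_validation("labels must be +1/-1")
  }
  structure(list(site_ids = as.character(site_ids),
                 labels = as.numeric(labels),
                 target_ptm = target_ptm),
            class = "ptm_dataset")
}

#' Confusion-matrix metric suite
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, precision
#' `TP/(TP+FP)`, accuracy `(TP+TN)/total` and the Matthews correlation
#' coefficient. A metric whose denominator is zero is reported as `NA`
#' and listed in the `undefined` field — it is never silently coerced to
#' zero, which would corrupt averages across folds.
#'
#' @param TP,TN,FP,FN Non-negative confusion counts.
#' @return A list with `Sn`, `Sp`, `Pre`, `Acc`, `MCC` and `undefined`
#'   (character vector of metrics with zero denominators).
#' @export
confusion_metrics <- function(TP, TN, FP, FN) {
  if (any(c(TP, TN, FP, FN) < 0)) stop_validation("counts must be >= 0")
  TP <- as.numeric(TP); TN <- as.numeric(TN)
  FP <- as.numeric(FP); FN <- as.numeric(FN)
  undef <- character()
  div <- function(num, den, name) {
    if (den == 0) { undef <<- c(undef, name); return(NA_real_) }
    num / den
  }
  Sn <- div(TP, TP + FN, "Sn")
  Sp <- div(TN, TN + FP, "Sp")
  Pre <- div(TP, TP + FP, "Pre")
  Acc <- div(TP + TN, TP + TN + FP + FN, "Acc")
  mcc_den <- sqrt((TP + FN) * (TP + FP) * (TN + FN) * (TN + FP))
  MCC <- if (mcc_den == 0) { undef <- c(undef, "MCC"); NA_real_ }
         else (TP * TN - FP * FN) / mcc_den
  list(Sn = Sn, Sp = Sp, Pre = Pre, Acc = Acc, MCC = MCC,
       undefined = undef)
}

# Confusion counts for the rule "score >= threshold is positive".
confusion_counts <- function(scores, labels, threshold = 0) {
  pos <- labels > 0
  pred <- scores >= threshold
  list(TP = sum(pred & pos), TN = sum(!pred & !pos),
       FP = sum(pred & !pos), FN = sum(!pred & pos))
}

#' ROC curve and AUC
#'
#' Builds the ROC curve by sweeping all distinct score values as
#' thresholds, with one vertex per distinct score (tied scores are
#' grouped), and computes the AUC by the trapezoidal rule. Under this
#' tie convention the AUC equals the Mann-Whitney concordance
#' probability with ties counted one half.
#'
#' @param scores Numeric decision scores, larger = more positive.
#' @param labels +1/-1 labels.
#' @return A list with `points` (data.frame `fpr`, `tpr`, from (0,0) to
#'   (1,1)) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- labels > 0
  P <- sum(pos); N <- sum(!pos)
  if (P == 0 || N == 0) stop_validation("both classes required for ROC")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- pos[ord]
  last <- cumsum(rle(s)$lengths)   # last index of each tie group
  tpr <- c(0, cumsum(y)[last] / P)
  fpr <- c(0, cumsum(!y)[last] / N)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Decision threshold anchored at a target specificity
#'
#' Scans the distinct observed scores in increasing order and returns
#' the smallest threshold at which the rule "score >= threshold is
#' positive" achieves empirical specificity of at least `sp_target`;
#' any strictly smaller admissible threshold would violate the target.
#' If no observed score qualifies (all negatives share the maximum
#' score) the threshold is `+Inf` with attribute `unreachable = TRUE`.
#'
#' @param scores Numeric scores.
#' @param labels +1/-1 labels.
#' @param sp_target Target specificity in `[0, 1)` (e.g. 0.95 for the
#'   medium and 0.99 for the high stringency level).
#' @return The threshold (numeric scalar, possibly `Inf`).
#' @export
threshold_at_specificity <- function(scores, labels, sp_target) {
  neg <- scores[labels < 0]
  if (length(neg) == 0L) stop_validation("no negative samples")
  for (t in sort(unique(scores))) {
    if (mean(neg < t) >= sp_target) return(t)
  }
  structure(Inf, unreachable = TRUE)
}

#' Fraction of true positives among the top-ranked p%
#'
#' Ranks all samples by score (descending), takes the top
#' `floor(p% * total)` and reports the number of positives found there
#' divided by the total number of positives.
#'
#' @param scores Numeric scores.
#' @param labels +1/-1 labels.
#' @param p Percentile in (0, 100].
#' @return Fraction in `[0, 1]`.
#' @export
top_fraction <- function(scores, labels, p) {
  if (p <= 0 || p > 100) stop_validation("p must be in (0, 100]")
  npos <- sum(labels > 0)
  if (npos == 0L) stop_validation("no positive samples")
  k <- floor(p / 100 * length(scores))
  top <- order(scores, decreasing = TRUE)[seq_len(k)]
  sum(labels[top] > 0) / npos
}

# Stratified fold assignment: within each class, indices are shuffled
# and dealt round-robin over the k folds. Deterministic given the seed;
# the caller's RNG state is untouched.
stratified_folds <- function(labels, k, seed) {
  if (length(labels) < k) stop_validation("fewer samples than folds")
  folds <- integer(length(labels))
  withr::with_seed(seed, {
    for (cls in unique(labels > 0)) {
      idx <- which((labels > 0) == cls)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Kernels and scores for a single cross-validation fold
#'
#' The work horse of [run_cv()], exposed so the fold-level computation
#' can be inspected directly (e.g. to audit that held-out target labels
#' cannot influence training). Given a precomputed raw sequence
#' similarity matrix and the full profile matrix it (a) normalises the
#' sequence kernel with constants from the training block only,
#' (b) masks the target-PTM column of test-site profiles and recomputes
#' the GIP kernel, (c) combines the kernels, trains, and scores the
#' test fold.
#'
#' @param S_seq Full raw similarity matrix over all sites.
#' @param profiles Full binary site x PTM matrix.
#' @param labels +1/-1 labels for all sites.
#' @param target_ptm Column of `profiles` under prediction.
#' @param train_idx,test_idx Integer row indices of the fold split.
#' @param config A [kernel_config()].
#' @param params A [model_params()].
#' @return A list with `scores` (test decision values), `model`,
#'   `K_train` and `K_cross`.
#' @export
cv_fold_scores <- function(S_seq, profiles, labels, target_ptm,
                           train_idx, test_idx, config, params) {
  if (length(unique(sign(labels[train_idx]))) < 2L) {
    stop_validation("training fold contains a single class")
  }
  nm <- minmax_normalize(S_seq[train_idx, train_idx, drop = FALSE])
  Kseq_cross <- apply_normalization(
    S_seq[test_idx, train_idx, drop = FALSE], nm$min_val, nm$max_val)

  masked <- mask_profiles(profiles, rownames(profiles)[test_idx], target_ptm)
  G <- gip_kernel(masked, config$gamma)
  Kgip_train <- G[train_idx, train_idx, drop = FALSE]
  Kgip_cross <- G[test_idx, train_idx, drop = FALSE]

  b <- config$betas
  K_train <- combine_kernels(list(nm$K, Kgip_train), b)
  if (isTRUE(config$psd_repair)) K_train <- nearest_psd(K_train)
  K_cross <- b[[1L]] * Kseq_cross + b[[2L]] * Kgip_cross

  model <- train_mksvm(K_train, labels[train_idx], params)
  scores <- decision_values(
    model, K_cross[, model$support_index, drop = FALSE])
  list(scores = scores, model = model, K_train = K_train, K_cross = K_cross)
}

#' Repeated stratified ten-fold cross-validation
#'
#' For each repeat the samples are partitioned into `folds` stratified
#' folds; per fold the kernels are rebuilt as described in
#' [cv_fold_scores()] (training-block normalisation, per-fold GIP
#' masking and recomputation), the SVM is trained on the training fold
#' and the held-out fold is scored. Scores are pooled within each
#' repeat; the confusion metrics (at decision threshold 0) and AUC are
#' computed per repeat, and the final report averages the repeats.
#'
#' @param windows Named character vector of peptide windows.
#' @param profiles Binary site x PTM matrix (rows aligned to windows).
#' @param data A [labeled_dataset()] aligned with `windows`.
#' @param config A [kernel_config()].
#' @param params A [model_params()].
#' @param folds Number of folds (default 10).
#' @param repeats Number of repeats (default 10).
#' @param seed Master seed; per-repeat fold seeds are derived from it.
#' @param aggregate `"pooled"` (default) computes each repeat's metrics
#'   on its pooled scores; `"per_fold"` computes metrics per fold and
#'   averages them within the repeat.
#' @return A list of class `ptm_cv`: `scores` (data.frame `site_id`,
#'   `repeat_`, `fold`, `label`, `score`), `per_repeat` (metrics
#'   data.frame), `average` (named list with `n_defined` counts),
#'   `fold_assignments` (repeats x sites matrix) and `settings`.
#' @export
run_cv <- function(windows, profiles, data, config = kernel_config(),
                   params = model_params(), folds = 10L, repeats = 10L,
                   seed = 1L, aggregate = c("pooled", "per_fold")) {
  aggregate <- match.arg(aggregate)
  m <- length(data$site_ids)
  if (!identical(names(windows), data$site_ids) ||
      !identical(rownames(profiles), data$site_ids)) {
    stop_validation("windows, profiles and dataset must share site ids ",
                    "in the same order")
  }
  if (m < folds) stop_validation("fewer samples than folds")

  S_seq <- seq_similarity_matrix(windows)
  rep_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                                 repeats))
  assign_mat <- matrix(NA_integer_, repeats, m,
                       dimnames = list(NULL, data$site_ids))
  score_rows <- vector("list", repeats)
  per_repeat <- vector("list", repeats)

  for (r in seq_len(repeats)) {
    fold_of <- stratified_folds(data$labels, folds, rep_seeds[r])
    assign_mat[r, ] <- fold_of
    scores <- numeric(m)
    fold_metrics <- vector("list", folds)
    for (f in seq_len(folds)) {
      te <- which(fold_of == f)
      tr <- which(fold_of != f)
      if (length(unique(sign(data$labels[tr]))) < 2L) {
        stop_validation("training data of fold ", f, " (repeat ", r,
                        ") contains a single class")
      }
      res <- cv_fold_scores(S_seq, profiles, data$labels, data$target_ptm,
                            tr, te, config, params)
      scores[te] <- res$scores
      if (aggregate == "per_fold") {
        cc <- confusion_counts(scores[te], data$labels[te])
        met <- confusion_metrics(cc$TP, cc$TN, cc$FP, cc$FN)
        met$AUC <- tryCatch(roc_auc(scores[te], data$labels[te])$auc,
                            error = function(e) NA_real_)
        fold_metrics[[f]] <- met
      }
    }
    if (aggregate == "pooled") {
      cc <- confusion_counts(scores, data$labels)
      met <- confusion_metrics(cc$TP, cc$TN, cc$FP, cc$FN)
      met$AUC <- roc_auc(scores, data$labels)$auc
    } else {
      met <- lapply(stats::setNames(nm = c("Sn", "Sp", "Pre", "Acc",
                                           "MCC", "AUC")),
                    function(nm2) {
                      v <- vapply(fold_metrics, function(fm)
                        as.numeric(fm[[nm2]]), numeric(1))
                      mean(v, na.rm = TRUE)
                    })
      met$undefined <- character()
    }
    per_repeat[[r]] <- data.frame(
      repeat_ = r, Sn = met$Sn, Sp = met$Sp, Pre = met$Pre,
      Acc = met$Acc, MCC = met$MCC, AUC = met$AUC)
    score_rows[[r]] <- data.frame(
      site_id = data$site_ids, repeat_ = r, fold = fold_of,
      label = data$labels, score = scores, stringsAsFactors = FALSE)
  }

  per_repeat <- do.call(rbind, per_repeat)
  metric_names <- c("Sn", "Sp", "Pre", "Acc", "MCC", "AUC")
  average <- lapply(stats::setNames(nm = metric_names), function(nm2)
    mean(per_repeat[[nm2]], na.rm = TRUE))
  n_defined <- vapply(metric_names, function(nm2)
    sum(!is.na(per_repeat[[nm2]])), integer(1))

  structure(list(
    scores = do.call(rbind, score_rows),
    per_repeat = per_repeat,
    average = average,
    n_defined = n_defined,
    fold_assignments = assign_mat,
    settings = list(folds = folds, repeats = repeats, seed = seed,
                    aggregate = aggregate, target_ptm = data$target_ptm,
                    gamma = config$gamma, betas = as.list(config$betas),
                    psd_repair = isTRUE(config$psd_repair),
                    C = params$C, balanced = params$balanced)
  ), class = "ptm_cv")
}

#' @export
print.ptm_cv <- function(x, ...) {
  s <- x$settings
  cat(sprintf("%d-fold cross-validation, %d repeat(s), seed %d\n",
              s$folds, s$repeats, s$seed))
  cat(sprintf("  target: %s   betas: seq=%g gip=%g   gamma=%g\n",
              s$target_ptm, s$betas[[1]], s$betas[[2]], s$gamma))
  avg <- unlist(x$average)
  cat("  averaged metrics:\n")
  print(round(avg, 4))
  invisible(x)
}

#' Export cross-validation results
#'
#' `cv_metrics_json` writes the per-repeat and averaged metrics with a
#' settings echo as JSON (full precision, no timestamps, so identical
#' runs produce byte-identical files). `cv_scores_tsv` writes one row
#' per (site, repeat) with fold, label and score. `roc_points_tsv`
#' writes a two-column FPR/TPR table for plotting.
#'
#' @param cv A `ptm_cv` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
cv_metrics_json <- function(cv, path) {
  obj <- list(settings = cv$settings,
              per_repeat = cv$per_repeat,
              average = cv$average,
              n_defined = as.list(cv$n_defined))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname cv_metrics_json
#' @export
cv_scores_tsv <- function(cv, path) {
  df <- cv$scores
  df$score <- format(df$score, digits = 17, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname cv_metrics_json
#' @param scores,labels Scores and +1/-1 labels for the ROC export.
#' @export
roc_points_tsv <- function(scores, labels, path) {
  pts <- roc_auc(scores, labels)$points
  utils::write.table(pts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
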