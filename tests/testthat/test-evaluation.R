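test_that("confusion metrics match the defining formulas", {
  m <- confusion_metrics(5, 5, 0, 0)
  expect_equal(unlist(m[c("Sn", "Sp", "Pre", "Acc", "MCC")]),
               c(Sn = 1, Sp = 1, Pre = 1, Acc = 1, MCC = 1))
  m <- confusion_metrics(25, 25, 25, 25)
  expect_equal(unlist(m[c("Sn", "Sp", "Pre", "Acc", "MCC")]),
               c(Sn = 0.5, Sp = 0.5, Pre = 0.5, Acc = 0.5, MCC = 0))
  m <- confusion_metrics(8, 7, 3, 2)
  expect_equal(m$Sn, 0.8)
  expect_equal(m$Sp, 0.7)
  expect_equal(m$Pre, 8 / 11)
  expect_equal(m$Acc, 0.75)
  expect_equal(m$MCC, (8 * 7 - 3 * 2) / sqrt(10 * 11 * 9 * 10))
})

test_that("zero-denominator metrics are flagged, never coerced to zero", {
  m <- confusion_metrics(0, 10, 0, 0)
  expect_true(is.na(m$Sn))
  expect_true(all(c("Sn", "Pre", "MCC") %in% m$undefined))
  expect_equal(m$Sp, 1)
  expect_error(confusion_metrics(-1, 0, 0, 0),
               class = "ptmkernels_validation_error")
})

test_that("ROC endpoints and AUC behave at the extremes", {
  scores <- c(0.9, 0.8, 0.2, 0.1)
  labels <- c(1, 1, -1, -1)
  r <- roc_auc(scores, labels)
  expect_equal(r$auc, 1)
  expect_equal(r$points[1, ], data.frame(fpr = 0, tpr = 0))
  expect_equal(unlist(r$points[nrow(r$points), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))
  # label-independent scores give chance-level AUC at large n
  withr::with_seed(1, {
    s <- rnorm(4000)
    y <- sample(c(-1, 1), 4000, replace = TRUE)
  })
  expect_lt(abs(roc_auc(s, y)$auc - 0.5), 0.03)
  expect_error(roc_auc(1:3, c(1, 1, 1)),
               class = "ptmkernels_validation_error")
})

test_that("AUC equals Mann-Whitney concordance, including under ties", {
  withr::with_seed(7, {
    for (i in 1:8) {
      n <- 60
      # coarse rounding forces heavy score ties
      s <- round(rnorm(n), sample(0:1, 1))
      y <- ifelse(runif(n) < plogis(s), 1, -1)
      if (length(unique(y)) < 2) next
      expect_equal(roc_auc(s, y)$auc, brute_concordance_auc(s, y),
                   tolerance = 1e-12)
    }
  })
})

test_that("specificity-anchored thresholds are minimal and sufficient", {
  scores <- c(0.1, 0.2, 0.8, 0.9)
  labels <- c(-1, -1, 1, 1)
  th <- threshold_at_specificity(scores, labels, 0.95)
  expect_equal(th, 0.8)  # smallest observed score with Sp >= 0.95
  expect_equal(threshold_at_specificity(scores, labels, 0), 0.1)
  # unreachable target: all negatives share the maximum score
  th <- threshold_at_specificity(c(1, 1, 0.5), c(-1, -1, 1), 0.5)
  expect_true(is.infinite(th))
  expect_true(attr(th, "unreachable"))
  # random instances: returned threshold achieves the target and the
  # next-lower distinct score does not
  withr::with_seed(19, {
    for (target in c(0.95, 0.99)) {
      s <- rnorm(500)
      y <- c(rep(1, 250), rep(-1, 250))
      th <- threshold_at_specificity(s, y, target)
      neg <- s[y < 0]
      expect_gte(mean(neg < th), target)
      lower <- max(s[s < th])
      expect_lt(mean(neg < lower), target)
    }
  })
})

test_that("raising the specificity target never raises sensitivity", {
  withr::with_seed(29, {
    for (i in 1:5) {
      s <- rnorm(400)
      y <- ifelse(runif(400) < plogis(1.5 * s), 1, -1)
      if (length(unique(y)) < 2) next
      sn_at <- function(tgt) {
        th <- threshold_at_specificity(s, y, tgt)
        sum(s >= th & y > 0) / sum(y > 0)
      }
      expect_gte(sn_at(0.95), sn_at(0.99))
    }
  })
})

test_that("top-fraction retrieval counts positives among the top p%", {
  scores <- c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1)
  labels <- c(1, -1, 1, 1, -1, -1, 1, -1, -1, -1)
  # top 20% of 10 samples = 2 samples, 1 of them positive, 4 positives
  expect_equal(top_fraction(scores, labels, 20), 0.25)
  expect_equal(top_fraction(scores, labels, 100), 1)
  # perfect ranking retrieves everything once the cutoff covers it
  expect_equal(top_fraction(scores, c(1, 1, 1, rep(-1, 7)), 30), 1)
  expect_error(top_fraction(scores, rep(-1, 10), 10),
               class = "ptmkernels_validation_error")
  expect_error(top_fraction(scores, labels, 0),
               class = "ptmkernels_validation_error")
})

test_that("stratified folds partition each class evenly and reproducibly", {
  y <- c(rep(1, 23), rep(-1, 77))
  f1 <- ptmkernels:::stratified_folds(y, 10, seed = 4)
  f2 <- ptmkernels:::stratified_folds(y, 10, seed = 4)
  expect_identical(f1, f2)
  expect_true(all(table(f1) %in% c(9, 10, 11)))
  for (k in 1:10) {
    expect_gte(sum(y[f1 == k] > 0), 2)  # class balance per fold
  }
})

test_that("run_cv scores every sample once per repeat and is deterministic", {
  dat <- generate_dataset(30, 30, strong_motif(), strong_network(), seed = 3)
  cv1 <- run_cv(dat$windows, dat$profiles, dat$dataset, kernel_config(),
                model_params(), folds = 5, repeats = 2, seed = 12)
  cv2 <- run_cv(dat$windows, dat$profiles, dat$dataset, kernel_config(),
                model_params(), folds = 5, repeats = 2, seed = 12)
  expect_identical(cv1, cv2)
  for (r in 1:2) {
    sub <- cv1$scores[cv1$scores$repeat_ == r, ]
    expect_setequal(sub$site_id, dat$dataset$site_ids)
    expect_equal(nrow(sub), 60)
  }
  # averaged metrics lie within the per-repeat range
  for (nm in c("Sn", "Sp", "AUC")) {
    v <- cv1$per_repeat[[nm]]
    expect_gte(cv1$average[[nm]], min(v) - 1e-12)
    expect_lte(cv1$average[[nm]], max(v) + 1e-12)
  }
  expect_error(run_cv(dat$windows, dat$profiles, dat$dataset,
                      folds = 100, seed = 1),
               class = "ptmkernels_validation_error")
})

test_that("per-fold metric aggregation is available behind a flag", {
  dat <- generate_dataset(25, 25, strong_motif(), strong_network(), seed = 13)
  cv <- run_cv(dat$windows, dat$profiles, dat$dataset, kernel_config(),
               model_params(), folds = 5, repeats = 1, seed = 2,
               aggregate = "per_fold")
  expect_true(is.finite(cv$average$AUC))
  expect_gte(cv$average$AUC, 0.5)
})

test_that("held-out target annotations cannot leak into fold kernels", {
  dat <- generate_dataset(40, 40, strong_motif(), strong_network(), seed = 6)
  S <- seq_similarity_matrix(dat$windows)
  fold_of <- ptmkernels:::stratified_folds(dat$dataset$labels, 5, seed = 9)
  te <- which(fold_of == 1); tr <- which(fold_of != 1)
  base <- cv_fold_scores(S, dat$profiles, dat$dataset$labels, "target",
                         tr, te, kernel_config(), model_params())
  # scramble the target-PTM annotations of the held-out sites
  scr <- dat$profiles
  withr::with_seed(1, scr[te, "target"] <- sample(c(0L, 1L), length(te),
                                                  replace = TRUE))
  alt <- cv_fold_scores(S, scr, dat$dataset$labels, "target",
                        tr, te, kernel_config(), model_params())
  expect_identical(alt$K_train, base$K_train)
  expect_identical(alt$K_cross, base$K_cross)
  expect_identical(alt$scores, base$scores)
})

test_that("candidate ranking is sorted and favours positive-like sites", {
  dat <- generate_dataset(30, 30, strong_motif(), strong_network(), seed = 25)
  m <- fit_mksvm(dat$windows, dat$profiles, dat$dataset,
                 params = model_params(probability = TRUE))
  # candidates cloned from a strong positive and a background negative
  cand_windows <- c("candA:11" = unname(dat$windows[1]),
                    "candB:11" = unname(dat$windows[60]))
  cand_profiles <- dat$profiles[c(1, 60), ]
  rownames(cand_profiles) <- c("candA:11", "candB:11")
  r <- rank_candidates(m, cand_windows, cand_profiles)
  expect_equal(r$site_id[1], "candA:11")
  expect_true(all(diff(r$probability) <= 0))
  expect_equal(r$rank, seq_len(nrow(r)))
  empty <- rank_candidates(m, character(0), cand_profiles[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("cv exports are written and re-readable", {
  dat <- generate_dataset(15, 15, strong_motif(), strong_network(), seed = 8)
  cv <- run_cv(dat$windows, dat$profiles, dat$dataset, kernel_config(),
               model_params(), folds = 3, repeats = 1, seed = 5)
  fj <- withr::local_tempfile(fileext = ".json")
  ft <- withr::local_tempfile(fileext = ".tsv")
  cv_metrics_json(cv, fj)
  cv_scores_tsv(cv, ft)
  obj <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(obj$average$AUC, cv$average$AUC, tolerance = 1e-12)
  tab <- read.delim(ft)
  expect_equal(nrow(tab), 30)
  fr <- withr::local_tempfile(fileext = ".tsv")
  sub <- cv$scores
  roc_points_tsv(sub$score, sub$label, fr)
  pts <- read.delim(fr)
  expect_equal(pts[1, ], data.frame(fpr = 0, tpr = 0))
})
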