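# Dual feasibility: the equality constraint and the class-weighted box
# constraints must hold for every fitted model.
expect_dual_feasible <- function(model, labels) {
  expect_lt(abs(sum(model$dual_coefs)), 1e-6)
  w <- ptmkernels:::class_weights(labels, model$params$balanced)
  box <- model$params$C *
    w[ifelse(labels[model$support_index] > 0, "+1", "-1")]
  expect_true(all(abs(model$dual_coefs) <= box + 1e-6))
}

test_that("training satisfies dual feasibility on a 2-point toy", {
  K <- diag(2); dimnames(K) <- list(c("a", "b"), c("a", "b"))
  m <- train_mksvm(K, c(1, -1), model_params(C = 1, balanced = FALSE))
  expect_dual_feasible(m, c(1, -1))
  expect_true(all(abs(m$dual_coefs) <= 1 + 1e-6))
})

test_that("a separable linear-kernel toy is fit to 100% training accuracy", {
  withr::with_seed(9, x <- c(runif(10, 1, 2), runif(10, -2, -1)))
  y <- c(rep(1, 10), rep(-1, 10))
  K <- outer(x, x)
  dimnames(K) <- list(sprintf("s%02d", 1:20), sprintf("s%02d", 1:20))
  m <- train_mksvm(K, y, model_params(C = 10))
  expect_dual_feasible(m, y)
  scores <- decision_values(m, K[, m$support_index, drop = FALSE])
  expect_true(all(sign(scores) == y))
})

test_that("balanced penalties follow the inverse-class-frequency rule", {
  y <- c(rep(1, 30), rep(-1, 10))
  w <- ptmkernels:::class_weights(y, balanced = TRUE)
  expect_equal(w[["+1"]], 40 / (2 * 30))
  expect_equal(w[["-1"]], 40 / (2 * 10))
  # total per-class penalty mass is equalised: N+ * C+ == N- * C-
  expect_equal(30 * w[["+1"]], 10 * w[["-1"]])
  # duplicating every negative leaves that equality intact
  y2 <- c(y, rep(-1, 10))
  w2 <- ptmkernels:::class_weights(y2, balanced = TRUE)
  expect_equal(35 * w2[["+1"]], 30 * w2[["+1"]] + 20 * w2[["-1"]] -
                 20 * w2[["-1"]] + 5 * w2[["+1"]])
  expect_equal(30 * w2[["+1"]], 20 * w2[["-1"]])
})

test_that("decision values equal the explicit kernel expansion", {
  withr::with_seed(13, {
    dat <- generate_dataset(25, 25, strong_motif(), strong_network(), seed = 2)
  })
  m <- fit_mksvm(dat$windows, dat$profiles, dat$dataset)
  expect_dual_feasible(m, dat$dataset$labels)
  S <- seq_similarity_matrix(dat$windows)
  nm <- minmax_normalize(S)
  G <- gip_kernel(dat$profiles, 0.001)
  K <- 0.5 * nm$K + 0.5 * G
  Kc <- K[, m$support_index, drop = FALSE]
  scores <- decision_values(m, Kc)
  # independent dot-product loop
  ref <- vapply(seq_len(nrow(Kc)), function(i)
    sum(Kc[i, ] * m$dual_coefs) + m$bias, numeric(1))
  expect_lt(max(abs(scores - ref)), 1e-10)
  # an all-zero kernel block scores everything at the bias
  Z <- matrix(0, 3, length(m$dual_coefs))
  expect_equal(unname(decision_values(m, Z)), rep(m$bias, 3))
  expect_error(decision_values(m, Z[, -1, drop = FALSE]),
               class = "ptmkernels_validation_error")
})

test_that("training rejects single-class data and size mismatches", {
  K <- diag(3)
  expect_error(train_mksvm(K, c(1, 1, 1), model_params()),
               "both classes", class = "ptmkernels_validation_error")
  expect_error(train_mksvm(K, c(1, -1), model_params()),
               class = "ptmkernels_validation_error")
})

test_that("beta selection reduces the combined model to a single kernel", {
  dat <- generate_dataset(20, 20, strong_motif(), strong_network(), seed = 31)
  S <- seq_similarity_matrix(dat$windows)
  nm <- minmax_normalize(S)
  G <- gip_kernel(dat$profiles, 0.001)
  y <- dat$dataset$labels
  for (betas in list(c(seq = 1, gip = 0), c(seq = 0, gip = 1))) {
    Kc <- combine_kernels(list(nm$K, G), betas)
    Ks <- if (betas[["seq"]] == 1) nm$K else G
    attr(Ks, "kind") <- NULL; attr(Kc, "kind") <- NULL
    m1 <- train_mksvm(Kc, y, model_params())
    m2 <- train_mksvm(Ks, y, model_params())
    s1 <- decision_values(m1, Kc[, m1$support_index, drop = FALSE])
    s2 <- decision_values(m2, Ks[, m2$support_index, drop = FALSE])
    expect_lt(max(abs(s1 - s2)), 1e-10)
  }
})

test_that("predictions are invariant to permuting the training order", {
  dat <- generate_dataset(20, 20, strong_motif(), strong_network(), seed = 17)
  S <- minmax_normalize(seq_similarity_matrix(dat$windows))$K
  G <- gip_kernel(dat$profiles, 0.001)
  K <- 0.5 * S + 0.5 * G
  y <- dat$dataset$labels
  tight <- model_params(tol = 1e-10)
  m1 <- train_mksvm(K, y, tight)
  withr::with_seed(1, perm <- sample(40))
  m2 <- train_mksvm(K[perm, perm], y[perm], tight)
  s1 <- decision_values(m1, K[, m1$support_index, drop = FALSE])
  s2 <- decision_values(m2, K[perm, perm][, m2$support_index, drop = FALSE])
  expect_lt(max(abs(s1[perm] - s2)), 1e-8)
})

test_that("scaling kernels by c and C by 1/c keeps the decision signs", {
  withr::with_seed(23, x <- c(runif(12, 0.5, 2), runif(12, -2, -0.5)))
  y <- rep(c(1, -1), each = 12)
  K <- outer(x, x)
  c0 <- 4
  m1 <- train_mksvm(K, y, model_params(C = 1, balanced = FALSE))
  m2 <- train_mksvm(c0 * K, y, model_params(C = 1 / c0, balanced = FALSE))
  s1 <- decision_values(m1, K[, m1$support_index, drop = FALSE])
  s2 <- decision_values(m2, c0 * K[, m2$support_index, drop = FALSE])
  expect_equal(sign(s1), sign(s2))
})

test_that("Platt probabilities are a strictly increasing map of scores", {
  dat <- generate_dataset(30, 30, strong_motif(), strong_network(), seed = 5)
  m <- fit_mksvm(dat$windows, dat$profiles, dat$dataset,
                 params = model_params(probability = TRUE, prob_seed = 3))
  expect_false(is.null(m$platt))
  withr::with_seed(2, scores <- rnorm(50))
  p <- predict_proba(m, scores)
  expect_true(all(p > 0 & p < 1))
  expect_equal(order(p), order(scores))
  # a symmetric sigmoid (zero intercept) maps score 0 to probability 0.5
  m0 <- m; m0$platt <- c(A = -2, B = 0)
  expect_equal(predict_proba(m0, 0), 0.5)
  m$platt <- NULL
  expect_error(predict_proba(m, scores),
               class = "ptmkernels_validation_error")
})

test_that("beta tuning scans the simplex and returns the best weights", {
  dat <- generate_dataset(20, 20, strong_motif(), strong_network(), seed = 51)
  tuned <- tune_betas(dat$windows, dat$profiles, dat$dataset,
                      grid = c(0, 0.5, 1), folds = 4, seed = 2)
  expect_equal(nrow(tuned$table), 3)
  expect_equal(tuned$table$beta_seq + tuned$table$beta_gip, rep(1, 3))
  expect_equal(unname(tuned$best[["seq"]] + tuned$best[["gip"]]), 1)
  expect_equal(max(tuned$table$auc),
               tuned$table$auc[tuned$table$beta_seq == tuned$best[["seq"]]])
})

test_that("model serialization round-trips scores exactly", {
  dat <- generate_dataset(25, 25, strong_motif(), strong_network(), seed = 41)
  m <- fit_mksvm(dat$windows, dat$profiles, dat$dataset,
                 params = model_params(probability = TRUE))
  cand <- generate_dataset(8, 8, strong_motif(), strong_network(), seed = 77)
  K <- ptmkernels:::candidate_kernel_block(m, cand$windows, cand$profiles)
  f <- withr::local_tempfile(fileext = ".json")
  write_model(m, f)
  m2 <- read_model(f)
  expect_equal(decision_values(m2, K), decision_values(m, K),
               tolerance = 1e-12)
  expect_equal(predict_proba(m2, 0.3), predict_proba(m, 0.3),
               tolerance = 1e-12)
  # version guard
  obj <- jsonlite::read_json(f, simplifyVector = TRUE)
  obj$version <- 99L
  f2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(obj, f2, auto_unbox = TRUE, digits = NA)
  expect_error(read_model(f2), "version",
               class = "ptmkernels_validation_error")
})
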