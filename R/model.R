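# SVM on a precomputed combined kernel.
#
# The classifier is a C-SVM (L1 soft margin) whose Gram matrix is the
# weighted kernel sum; kernlab's ksvm solves the dual with the kernel
# supplied as a matrix. Class imbalance is handled with per-class
# penalties C_+- = C * N / (2 * N_+-), which reduce to a uniform C on
# balanced data. Probabilities come from Platt scaling fitted on
# cross-validated decision values of the training set.

#' Training parameters
#'
#' @param C Regularization parameter of the soft-margin SVM (default 1,
#'   the solver's default).
#' @param balanced Use inverse-class-frequency penalties
#'   `C_+- = C * N / (2 * N_+-)` (default `TRUE`).
#' @param probability Fit a Platt sigmoid on internally cross-validated
#'   decision values so the model can emit probabilities.
#' @param prob_seed Seed for the internal cross-validation used by the
#'   Platt fit (it shuffles the training set).
#' @param prob_folds Folds of that internal cross-validation (default 3).
#' @param tol Convergence tolerance of the dual solver (default 0.001,
#'   the solver's own default).
#' @return A list of class `ptm_model_params`.
#' @export
model_params <- function(C = 1, balanced = TRUE, probability = FALSE,
                         prob_seed = 1L, prob_folds = 3L, tol = 0.001) {
  if (!is.numeric(C) || C <= 0) stop_validation("C must be positive")
  structure(list(C = C, balanced = balanced, probability = probability,
                 prob_seed = as.integer(prob_seed),
                 prob_folds = as.integer(prob_folds), tol = tol),
            class = "ptm_model_params")
}

# Per-class penalties as a named vector over the internal factor levels.
class_weights <- function(labels, balanced) {
  n <- length(labels)
  npos <- sum(labels > 0)
  nneg <- n - npos
  if (balanced) {
    c("-1" = n / (2 * nneg), "+1" = n / (2 * npos))
  } else {
    c("-1" = 1, "+1" = 1)
  }
}

#' Train an SVM on a precomputed kernel
#'
#' Solves the L1 soft-margin dual on the supplied Gram matrix. The
#' returned model stores the signed dual coefficients `a_i * y_i` of the
#' support sites and the bias, so a decision value is
#' `sum_j a_j y_j K(t, x_j) + b`. Dual feasibility (`sum a_i y_i = 0`,
#' `0 <= a_i <= C_i`) is checked after every fit.
#'
#' @param K_train Symmetric kernel matrix aligned with `labels`.
#' @param labels Numeric vector of +1/-1.
#' @param params A [model_params()] object.
#' @param keep For use by higher-level fitters: a list of extras
#'   (support windows, profiles, normalisation constants, kernel config)
#'   stored on the model for later out-of-sample kernel construction.
#' @return A list of class `ptm_svm` with elements `dual_coefs`, `bias`,
#'   `support_ids`, `support_index`, `params`, `platt` and any extras.
#' @export
train_mksvm <- function(K_train, labels, params = model_params(),
                        keep = list()) {
  m <- length(labels)
  if (nrow(K_train) != m || ncol(K_train) != m) {
    stop_validation("kernel size does not match number of labels")
  }
  if (length(unique(sign(labels))) < 2L) {
    stop_validation("training data must contain both classes")
  }
  y <- factor(ifelse(labels > 0, "+1", "-1"), levels = c("-1", "+1"))
  w <- class_weights(labels, params$balanced)
  tol <- if (is.null(params$tol)) 0.001 else params$tol
  fit <- kernlab::ksvm(kernlab::as.kernelMatrix(unname(K_train)), y,
                       type = "C-svc", C = params$C, class.weights = w,
                       tol = tol, prob.model = FALSE)
  sv <- kernlab::SVindex(fit)
  dual <- unlist(kernlab::coef(fit))
  bias <- -kernlab::b(fit)
  # dual feasibility (box constraints and the equality constraint)
  alpha <- abs(dual)
  box <- params$C * w[as.character(y[sv])]
  if (abs(sum(dual)) > 1e-6 || any(alpha > box + 1e-6)) {
    stop("solver returned a dual-infeasible solution")
  }
  ids <- rownames(K_train)
  model <- structure(c(list(
    dual_coefs = dual,
    bias = bias,
    support_index = sv,
    support_ids = if (is.null(ids)) as.character(sv) else ids[sv],
    n_train = m,
    params = params,
    platt = NULL
  ), keep), class = "ptm_svm")
  if (isTRUE(params$probability)) {
    model$platt <- platt_cv_fit(K_train, labels, params)
  }
  model
}

#' Decision values from a cross-kernel block
#'
#' @param model A `ptm_svm` model.
#' @param K_cross Rectangular kernel block, rows = query sites, columns
#'   aligned with `model$support_ids`.
#' @return Numeric decision scores, one per query row.
#' @export
decision_values <- function(model, K_cross) {
  if (ncol(K_cross) != length(model$dual_coefs)) {
    stop_validation("K_cross columns do not match the support set")
  }
  if (!is.null(colnames(K_cross)) &&
      !identical(colnames(K_cross), model$support_ids)) {
    stop_validation("K_cross column ids do not match the support ids")
  }
  drop(K_cross %*% model$dual_coefs) + model$bias
}

# ---- Platt scaling -------------------------------------------------------

# Newton fit of P(y=1|s) = 1 / (1 + exp(A*s + B)) with the regularised
# targets of Platt (1999) as stabilised by Lin, Weng & Keerthi (2007).
platt_fit <- function(scores, labels) {
  t1 <- sum(labels > 0)
  t0 <- sum(labels <= 0)
  hi <- (t1 + 1) / (t1 + 2)
  lo <- 1 / (t0 + 2)
  t <- ifelse(labels > 0, hi, lo)
  A <- 0
  B <- log((t0 + 1) / (t1 + 1))
  for (it in 1:100) {
    fApB <- A * scores + B
    p <- ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)),
                1 / (1 + exp(fApB)))
    q <- 1 - p
    d1 <- t - p          # gradient pieces (note p decreases in fApB)
    g1 <- sum(scores * d1)
    g2 <- sum(d1)
    if (abs(g1) < 1e-5 && abs(g2) < 1e-5) break
    d2 <- p * q
    h11 <- sum(scores * scores * d2) + 1e-12
    h22 <- sum(d2) + 1e-12
    h21 <- sum(scores * d2)
    det <- h11 * h22 - h21 * h21
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    # backtracking line search on the cross-entropy
    nll <- function(A, B) {
      f <- A * scores + B
      sum(ifelse(f >= 0, t * f + log1p(exp(-f)), (t - 1) * f + log1p(exp(f))))
    }
    base <- nll(A, B)
    step <- 1
    while (step >= 1e-10) {
      if (nll(A + step * dA, B + step * dB) < base + 1e-4 * step *
            (g1 * dA + g2 * dB)) break
      step <- step / 2
    }
    A <- A + step * dA
    B <- B + step * dB
  }
  # the probability map must be strictly increasing in the score
  if (A >= 0) A <- -1e-8
  c(A = A, B = B)
}

# Platt sigmoid on decision values obtained by stratified k-fold CV
# within the training set, so the sigmoid is not fitted on resubstitution
# scores.
platt_cv_fit <- function(K_train, labels, params) {
  folds <- stratified_folds(labels, params$prob_folds, params$prob_seed)
  scores <- numeric(length(labels))
  inner <- model_params(C = params$C, balanced = params$balanced,
                        probability = FALSE)
  for (f in seq_len(params$prob_folds)) {
    te <- which(folds == f)
    tr <- which(folds != f)
    sub <- train_mksvm(K_train[tr, tr, drop = FALSE], labels[tr], inner)
    scores[te] <- decision_values(
      sub, K_train[te, tr[sub$support_index], drop = FALSE])
  }
  platt_fit(scores, labels)
}

#' Convert decision scores to probabilities
#'
#' Applies the model's Platt sigmoid, a strictly increasing map of the
#' decision score into (0, 1); the probability ordering therefore equals
#' the score ordering.
#'
#' @param model A `ptm_svm` trained with `probability = TRUE`.
#' @param scores Decision values.
#' @return Probabilities in (0, 1).
#' @export
predict_proba <- function(model, scores) {
  if (is.null(model$platt)) {
    stop_validation("model was trained without probability = TRUE")
  }
  1 / (1 + exp(model$platt[["A"]] * scores + model$platt[["B"]]))
}

# ---- serialization -------------------------------------------------------

MODEL_FORMAT_VERSION <- 1L

#' Save / load a trained model
#'
#' The model is stored as a single self-describing JSON file (format
#' versioned, full numeric precision) holding the dual coefficients,
#' bias, support ids, support windows and profiles, normalisation
#' constants, kernel configuration and the Platt map. A load/save round
#' trip reproduces decision scores exactly.
#'
#' @param model A `ptm_svm`.
#' @param path File path.
#' @return `write_model` returns `path` invisibly; `read_model` returns
#'   the model.
#' @export
write_model <- function(model, path) {
  obj <- list(
    format = "ptmkernels-model",
    version = MODEL_FORMAT_VERSION,
    dual_coefs = unname(model$dual_coefs),
    bias = model$bias,
    support_index = model$support_index,
    support_ids = model$support_ids,
    n_train = model$n_train,
    params = unclass(model$params),
    platt = if (is.null(model$platt)) NULL else as.list(model$platt),
    norm_constants = model$norm_constants,
    config = if (is.null(model$config)) NULL else unclass(model$config),
    support_windows = as.list(model$support_windows),
    support_profiles = if (is.null(model$support_profiles)) NULL else list(
      site_ids = rownames(model$support_profiles),
      ptm_names = colnames(model$support_profiles),
      rows = unname(apply(model$support_profiles, 1L, as.integer,
                          simplify = FALSE))
    ),
    target_ptm = model$target_ptm
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "ptmkernels-model")) {
    stop_validation(path, " is not a ptmkernels model file")
  }
  if (obj$version > MODEL_FORMAT_VERSION) {
    stop_validation("model format version ", obj$version,
                    " is newer than supported (", MODEL_FORMAT_VERSION, ")")
  }
  model <- list(
    dual_coefs = as.numeric(obj$dual_coefs),
    bias = obj$bias,
    support_index = as.integer(obj$support_index),
    support_ids = as.character(obj$support_ids),
    n_train = obj$n_train,
    params = structure(as.list(obj$params), class = "ptm_model_params"),
    platt = if (is.null(obj$platt)) NULL else
      c(A = obj$platt$A, B = obj$platt$B),
    norm_constants = if (is.null(obj$norm_constants)) NULL else
      as.numeric(obj$norm_constants),
    config = if (is.null(obj$config)) NULL else
      structure(as.list(obj$config), class = "ptm_kernel_config"),
    target_ptm = obj$target_ptm
  )
  if (!is.null(obj$support_windows) && length(obj$support_windows) > 0) {
    model$support_windows <- unlist(obj$support_windows)
    names(model$support_windows) <- model$support_ids
  }
  if (!is.null(obj$support_profiles)) {
    sp <- obj$support_profiles
    rows <- if (is.list(sp$rows)) do.call(rbind, sp$rows) else sp$rows
    A <- matrix(as.integer(rows), nrow = length(sp$site_ids),
                dimnames = list(sp$site_ids, sp$ptm_names))
    model$support_profiles <- A
  }
  if (!is.null(model$config)) {
    model$config$betas <- unlist(model$config$betas)
  }
  structure(model, class = "ptm_svm")
}

#' @export
print.ptm_svm <- function(x, ...) {
  cat("Multiple-kernel SVM (precomputed kernel)\n")
  cat("  training sites:", x$n_train,
      "  support vectors:", length(x$dual_coefs), "\n")
  cat("  bias:", format(x$bias, digits = 6),
      "  probability model:", !is.null(x$platt), "\n")
  if (!is.null(x$config)) {
    cat("  betas:", paste(names(x$config$betas), "=",
                          format(x$config$betas), collapse = ", "),
        "  gamma:", x$config$gamma, "\n")
  }
  invisible(x)
}
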