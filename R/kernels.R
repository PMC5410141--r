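# Kernel construction.
#
# Two site-by-site kernels feed the classifier:
#   * the local sequence kernel: positionwise BLOSUM62 similarity of the
#     21-residue windows, min-max normalised to [0, 1];
#   * the Gaussian interaction-profile (GIP) kernel: an RBF kernel on
#     the binary rows of the site x PTM adjacency matrix.
# Both are combined as a non-negative weighted sum before training.

#' Kernel and combination configuration
#'
#' @param gamma Bandwidth of the Gaussian interaction-profile kernel
#'   (default 0.001).
#' @param betas Non-negative weights of the component kernels, named
#'   `seq` and `gip`; at least one must be positive. Default `(0.5, 0.5)`.
#' @param psd_repair If `TRUE`, the combined kernel is projected onto the
#'   positive semidefinite cone with [nearest_psd()] before training.
#'   Off by default: the GIP kernel is PSD by construction and the
#'   normalised sequence kernel is passed to the solver as-is.
#' @return A list of class `ptm_kernel_config`.
#' @export
kernel_config <- function(gamma = 0.001,
                          betas = c(seq = 0.5, gip = 0.5),
                          psd_repair = FALSE) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0) {
    stop_validation("gamma must be a positive scalar")
  }
  if (any(betas < 0) || all(betas == 0)) {
    stop_validation("betas must be non-negative with at least one positive")
  }
  if (is.null(names(betas))) names(betas) <- c("seq", "gip")[seq_along(betas)]
  structure(list(gamma = gamma, betas = betas, psd_repair = psd_repair),
            class = "ptm_kernel_config")
}

#' Raw BLOSUM62 similarity matrix over peptide windows
#'
#' Entry (i, j) is the sum over the 21 window positions of the BLOSUM62
#' score between the aligned residues of windows i and j. The result is
#' an exact, symmetric, integer-valued matrix.
#'
#' @param windows Named character vector of equal-length windows.
#' @return An m x m numeric matrix with `site_id` dimnames and attribute
#'   `kind = "raw_similarity"`.
#' @export
seq_similarity_matrix <- function(windows) {
  enc <- encode_windows(windows)
  B <- blosum62_matrix()
  m <- nrow(enc)
  S <- matrix(0, m, m)
  # one vectorised m x m accumulation per window position
  for (x in seq_len(ncol(enc))) {
    S <- S + B[enc[, x], enc[, x]]
  }
  dimnames(S) <- list(rownames(enc), rownames(enc))
  attr(S, "kind") <- "raw_similarity"
  S
}

#' Min-max normalisation of a similarity matrix
#'
#' Maps every entry through `(S - min(S)) / (max(S) - min(S))`, with the
#' minimum and maximum taken over all entries, so the result lies in
#' [0, 1] and similarities become non-negative. The constants are
#' returned so the identical affine map can later be applied to
#' out-of-sample similarity blocks.
#'
#' @param S A raw similarity matrix.
#' @return A list with `K` (normalised matrix, attribute
#'   `kind = "seq_kernel"`), `min_val` and `max_val`.
#' @export
minmax_normalize <- function(S) {
  lo <- min(S)
  hi <- max(S)
  if (hi == lo) {
    stop_validation("similarity matrix is constant; normalization undefined")
  }
  K <- (S - lo) / (hi - lo)
  attr(K, "kind") <- "seq_kernel"
  list(K = K, min_val = lo, max_val = hi)
}

#' Apply stored normalisation constants to a cross-similarity block
#'
#' Applies the affine map from [minmax_normalize()] to a rectangular
#' (e.g. test x train) similarity block, clamping to [0, 1] since
#' out-of-sample similarities can exceed the training range.
#'
#' @param S_cross Rectangular raw similarity block.
#' @param min_val,max_val Constants from [minmax_normalize()].
#' @return The normalised, clamped block.
#' @export
apply_normalization <- function(S_cross, min_val, max_val) {
  if (max_val <= min_val) stop_validation("max_val must exceed min_val")
  K <- (S_cross - min_val) / (max_val - min_val)
  pmin(pmax(K, 0), 1)
}

#' Build the site x PTM interaction-profile (adjacency) matrix
#'
#' Row i is the binary interaction profile of site i: entry (i, j) is 1
#' exactly when annotation j appears in the site's annotation set.
#'
#' @param sites A data.frame from [read_site_table()].
#' @param ptm_names Optional character vector fixing the column set and
#'   order; defaults to the sorted union of all annotations seen.
#' @return A binary integer matrix with `site_id` rownames and PTM-name
#'   colnames.
#' @export
profiles_from_sites <- function(sites, ptm_names = NULL) {
  if (is.null(ptm_names)) {
    ptm_names <- sort(unique(unlist(sites$annotations)))
  }
  A <- matrix(0L, nrow(sites), length(ptm_names),
              dimnames = list(sites$site_id, ptm_names))
  for (i in seq_len(nrow(sites))) {
    hit <- intersect(sites$annotations[[i]], ptm_names)
    A[i, hit] <- 1L
  }
  A
}

#' Gaussian interaction-profile kernel
#'
#' Entry (i, j) is `exp(-gamma * ||A_i - A_j||^2)` where `A_i` is the
#' binary interaction profile (row) of site i; for binary profiles the
#' squared Euclidean distance equals the Hamming distance. The kernel is
#' positive semidefinite with unit diagonal.
#'
#' @param profiles Binary site x PTM matrix.
#' @param gamma Positive bandwidth (default 0.001).
#' @return An m x m kernel matrix, attribute `kind = "gip_kernel"`.
#' @export
gip_kernel <- function(profiles, gamma = 0.001) {
  if (!all(profiles %in% c(0, 1))) {
    stop_validation("interaction profiles must be binary")
  }
  if (gamma <= 0) stop_validation("gamma must be positive")
  A <- matrix(as.numeric(profiles), nrow(profiles), ncol(profiles),
              dimnames = dimnames(profiles))
  rs <- rowSums(A)
  # ||a_i - a_j||^2 = |a_i| + |a_j| - 2 <a_i, a_j> for binary rows
  d2 <- outer(rs, rs, "+") - 2 * tcrossprod(A)
  d2[d2 < 0] <- 0  # numerical guard
  K <- exp(-gamma * d2)
  attr(K, "kind") <- "gip_kernel"
  K
}

#' Mask the target-PTM annotations of held-out sites
#'
#' Under cross-validation the adjacency matrix must not carry the very
#' labels being predicted: the target-PTM column is zeroed for every
#' test site. Training sites keep all annotations, and test sites keep
#' their annotations for *other* modifications — those cross-PTM
#' relationships are the information the GIP kernel is designed to use.
#'
#' @param profiles Binary site x PTM matrix.
#' @param test_site_ids Site ids of the held-out fold.
#' @param target_ptm Column name of the modification under prediction.
#' @return A copy of `profiles` with the masked entries set to 0.
#' @export
mask_profiles <- function(profiles, test_site_ids, target_ptm) {
  if (!(target_ptm %in% colnames(profiles))) {
    stop_validation("unknown target PTM: ", target_ptm)
  }
  unknown <- setdiff(test_site_ids, rownames(profiles))
  if (length(unknown) > 0L) {
    stop_validation("unknown site id(s): ", paste(unknown, collapse = ", "))
  }
  out <- profiles
  out[test_site_ids, target_ptm] <- 0L
  out
}

#' Non-negative weighted sum of component kernels
#'
#' @param components List of kernel matrices sharing the same site ids
#'   in the same order.
#' @param betas Non-negative weights, one per component.
#' @return The combined matrix, attribute `kind = "combined"`.
#' @export
combine_kernels <- function(components, betas) {
  if (length(components) != length(betas)) {
    stop_validation("need one beta per component kernel")
  }
  if (any(betas < 0)) stop_validation("betas must be non-negative")
  ref <- dimnames(components[[1L]])
  for (K in components[-1L]) {
    if (!identical(dimnames(K), ref)) {
      stop_validation("component kernels disagree on site ids or order")
    }
  }
  out <- matrix(0, nrow(components[[1L]]), ncol(components[[1L]]),
                dimnames = ref)
  for (d in seq_along(components)) {
    out <- out + betas[d] * components[[d]]
  }
  attr(out, "kind") <- "combined"
  out
}

#' Project a symmetric matrix onto the positive semidefinite cone
#'
#' Clips negative eigenvalues to zero and reconstructs. A matrix that is
#' already PSD is returned unchanged up to numerical noise. Available as
#' an optional guard because the min-max normalised BLOSUM62 similarity
#' is not guaranteed PSD, while SVM solvers assume a valid Gram matrix.
#'
#' @param K Symmetric matrix.
#' @return The nearest (Frobenius) PSD matrix.
#' @export
nearest_psd <- function(K) {
  if (!isSymmetric(unname(K), tol = 1e-8)) {
    stop_validation("nearest_psd requires a symmetric matrix")
  }
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  if (min(e$values) >= 0) return(K)
  lam <- pmax(e$values, 0)
  out <- e$vectors %*% (lam * t(e$vectors))
  out <- (out + t(out)) / 2
  dimnames(out) <- dimnames(K)
  attr(out, "kind") <- attr(K, "kind")
  out
}

# ---- serialization -------------------------------------------------------

#' Write / read a kernel matrix as TSV
#'
#' Full-precision (17 significant digits) TSV with a header row of site
#' ids and one row per site, so a write/read round trip is lossless.
#'
#' @param K Kernel matrix with dimnames.
#' @param path Output path.
#' @return `write_kernel_tsv` returns `path` invisibly; `read_kernel_tsv`
#'   returns the matrix.
#' @export
write_kernel_tsv <- function(K, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("site_id", colnames(K)), collapse = "\t"), con)
  body <- apply(K, 1L, function(r) {
    paste(format(r, digits = 17, scientific = TRUE, trim = TRUE),
          collapse = "\t")
  })
  writeLines(paste(rownames(K), body, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_kernel_tsv
#' @export
read_kernel_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  K <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(K) <- tab[[1L]]
  K
}

#' Write / read an adjacency matrix
#'
#' `write_adjacency_dense`/`read_adjacency_dense` use a dense TSV (site
#' rows, PTM columns). `write_adjacency_edges` writes the edge list
#' (`site_id`, `ptm_name`) of all 1-entries; reading an edge list needs
#' the full site and PTM universes to restore the 0 rows/columns.
#'
#' @param A Binary site x PTM matrix.
#' @param path File path.
#' @param site_ids,ptm_names Universes used to reconstruct the dense
#'   matrix from an edge list.
#' @return Writers return `path` invisibly; readers return the matrix.
#' @export
write_adjacency_dense <- function(A, path) {
  df <- data.frame(site_id = rownames(A), A, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_adjacency_dense
#' @export
read_adjacency_dense <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  A <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(A) <- "integer"
  rownames(A) <- tab[[1L]]
  A
}

#' @rdname write_adjacency_dense
#' @export
write_adjacency_edges <- function(A, path) {
  idx <- which(A == 1L, arr.ind = TRUE)
  df <- data.frame(site_id = rownames(A)[idx[, 1L]],
                   ptm_name = colnames(A)[idx[, 2L]],
                   stringsAsFactors = FALSE)
  df <- df[order(df$site_id, df$ptm_name), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_adjacency_dense
#' @export
read_adjacency_edges <- function(path, site_ids, ptm_names) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  A <- matrix(0L, length(site_ids), length(ptm_names),
              dimnames = list(site_ids, ptm_names))
  unknown <- setdiff(tab$site_id, site_ids)
  if (length(unknown) > 0L) {
    stop_validation("edge list references unknown site id(s): ",
                    paste(unknown, collapse = ", "))
  }
  A[cbind(tab$site_id, tab$ptm_name)] <- 1L
  A
}
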