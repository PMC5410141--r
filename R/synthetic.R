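# Synthetic motif-and-network datasets.
#
# Real PTM sites carry two distinguishable signals: a conserved local
# sequence motif around the modified residue, and correlated membership
# in the site-modification network (a site carrying one modification is
# more likely to carry related ones). The generator emulates both with
# controllable strength, so every pipeline stage — window extraction,
# both kernels, training, cross-validation — can be exercised, from
# zero signal (a calibration null) up to near-separable data.

#' Motif specification for positive windows
#'
#' Positive windows are drawn from a consensus pattern: at each
#' specified (non-wildcard) position the consensus residue is emitted
#' with probability `match_prob`, otherwise a residue is drawn from the
#' background frequencies. Wildcard positions and all negative-window
#' positions are pure background. The central position (11 of 21) is
#' always the target residue, for positives and negatives alike.
#'
#' @param target_residue `"S"`, `"T"` or `"Y"`.
#' @param consensus Length-21 pattern; `"."` marks wildcard positions.
#'   Default: a fixed, fully specified arginine-rich kinase-like motif
#'   around the target residue.
#' @param match_prob Per-position probability that a positive window
#'   carries the consensus residue.
#' @param background_freqs Named numeric vector of residue frequencies
#'   over the 20 standard residues, summing to 1. Default uniform; see
#'   [aa_background()] for a natural-abundance alternative.
#' @return A list of class `ptm_motif_spec`.
#' @export
motif_spec <- function(target_residue = "S",
                       consensus = default_consensus(target_residue),
                       match_prob = 0.8,
                       background_freqs = aa_background("uniform")) {
  if (!(target_residue %in% c("S", "T", "Y"))) {
    stop_validation("target_residue must be S, T or Y")
  }
  if (nchar(consensus) != 21L) {
    stop_validation("consensus must have length 21")
  }
  if (substr(consensus, 11L, 11L) != target_residue) {
    stop_validation("consensus position 11 must be the target residue")
  }
  if (match_prob < 0 || match_prob > 1) {
    stop_validation("match_prob must be in [0, 1]")
  }
  if (!setequal(names(background_freqs), AA_STANDARD) ||
      abs(sum(background_freqs) - 1) > 1e-9 || any(background_freqs < 0)) {
    stop_validation("background_freqs must be frequencies over the 20 ",
                    "standard residues summing to 1")
  }
  structure(list(target_residue = target_residue, consensus = consensus,
                 match_prob = match_prob,
                 background_freqs = background_freqs[AA_STANDARD]),
            class = "ptm_motif_spec")
}

#' Default fully specified consensus motif
#'
#' A fixed, arbitrary but realistic-looking basophilic 21-mer used as
#' the default positive-class consensus; only the central residue
#' varies with the target.
#'
#' @param target_residue `"S"`, `"T"` or `"Y"`.
#' @return A 21-character string.
#' @export
default_consensus <- function(target_residue = "S") {
  paste0("GKRRNSLRRA", target_residue, "LGEDVKPTFY")
}

#' Background amino-acid frequencies
#'
#' @param kind `"uniform"` (default; 1/20 each) or `"swissprot"`
#'   (approximate natural abundances in the UniProtKB/Swiss-Prot
#'   release statistics, renormalised).
#' @return Named numeric vector over the 20 standard residues.
#' @export
aa_background <- function(kind = c("uniform", "swissprot")) {
  kind <- match.arg(kind)
  if (kind == "uniform") {
    return(stats::setNames(rep(1 / 20, 20), AA_STANDARD))
  }
  f <- c(A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.37, Q = 3.93,
         E = 6.75, G = 7.07, H = 2.27, I = 5.96, L = 9.66, K = 5.84,
         M = 2.42, F = 3.86, P = 4.70, S = 6.56, T = 5.34, W = 1.08,
         Y = 2.92, V = 6.87)
  (f / sum(f))[AA_STANDARD]
}

#' Site-modification network specification
#'
#' Controls the bipartite annotations: besides the target PTM column
#' (1 for positives, 0 for negatives when `target_included`), each of
#' `n_ptms - 1` helper modifications is carried independently with
#' probability `co_occurrence_prob` by positives and `background_prob`
#' by negatives. Setting the two probabilities equal removes all
#' network signal.
#'
#' @param n_ptms Total number of PTM columns, including the target.
#' @param co_occurrence_prob Helper-annotation probability for positives.
#' @param background_prob Helper-annotation probability for negatives.
#' @param target_included Include the target column in generated
#'   profiles (it is masked during cross-validation).
#' @param target_name Name of the target PTM column.
#' @return A list of class `ptm_network_spec`.
#' @export
network_spec <- function(n_ptms = 5L, co_occurrence_prob = 0.3,
                         background_prob = 0.05, target_included = TRUE,
                         target_name = "target") {
  if (n_ptms < 1L) stop_validation("n_ptms must be >= 1")
  if (background_prob < 0 || co_occurrence_prob > 1 ||
      background_prob > co_occurrence_prob) {
    stop_validation("need 0 <= background_prob <= co_occurrence_prob <= 1")
  }
  structure(list(n_ptms = as.integer(n_ptms),
                 co_occurrence_prob = co_occurrence_prob,
                 background_prob = background_prob,
                 target_included = target_included,
                 target_name = target_name),
            class = "ptm_network_spec")
}

sample_windows <- function(n, motif, positive) {
  cons <- strsplit(motif$consensus, "")[[1L]]
  freqs <- motif$background_freqs
  out <- matrix(
    sample(AA_STANDARD, n * 21L, replace = TRUE, prob = freqs),
    nrow = n)
  if (positive) {
    for (x in which(cons != ".")) {
      hit <- stats::runif(n) < motif$match_prob
      out[hit, x] <- cons[x]
    }
  }
  out[, 11L] <- motif$target_residue
  apply(out, 1L, paste, collapse = "")
}

#' Generate a synthetic labeled dataset
#'
#' Draws `n_pos` motif-bearing positive windows and `n_neg` background
#' negative windows (all with the correct central residue), attaches
#' correlated bipartite annotations per the network spec, and packages
#' everything in the same containers the real readers produce: a
#' protein table (each window embedded as its own 21-residue protein,
#' site at position 11), a site table, the profile matrix and a
#' [labeled_dataset()]. Fully reproducible from the seed.
#'
#' @param n_pos,n_neg Positive/negative sample counts (each >= 1).
#' @param motif A [motif_spec()].
#' @param network A [network_spec()].
#' @param seed Integer seed; all randomness flows from it.
#' @return A list with `proteins`, `sites`, `windows`, `profiles`,
#'   `dataset`.
#' @export
generate_dataset <- function(n_pos, n_neg, motif = motif_spec(),
                             network = network_spec(), seed = 1L) {
  if (n_pos < 1L || n_neg < 1L) {
    stop_validation("n_pos and n_neg must be >= 1")
  }
  n <- n_pos + n_neg
  withr::with_seed(seed, {
    win <- c(sample_windows(n_pos, motif, positive = TRUE),
             sample_windows(n_neg, motif, positive = FALSE))
    labels <- c(rep(1, n_pos), rep(-1, n_neg))
    prot_ids <- sprintf("SYNP%04d", seq_len(n))
    site_ids <- paste0(prot_ids, ":11")
    names(win) <- site_ids

    helpers <- if (network$n_ptms > 1L) {
      paste0("helper", seq_len(network$n_ptms - 1L))
    } else character()
    ptm_names <- c(network$target_name, helpers)
    A <- matrix(0L, n, network$n_ptms,
                dimnames = list(site_ids, ptm_names))
    if (network$target_included) {
      A[labels > 0, network$target_name] <- 1L
    }
    for (h in helpers) {
      p <- ifelse(labels > 0, network$co_occurrence_prob,
                  network$background_prob)
      A[, h] <- as.integer(stats::runif(n) < p)
    }
  })
  ann <- lapply(seq_len(n), function(i) colnames(A)[A[i, ] == 1L])
  proteins <- data.frame(id = prot_ids, sequence = unname(win),
                         stringsAsFactors = FALSE)
  sites <- data.frame(site_id = site_ids, protein_id = prot_ids,
                      position = 11L, residue = motif$target_residue,
                      annotations = I(ann), task_label = as.integer(labels),
                      stringsAsFactors = FALSE)
  list(proteins = proteins, sites = sites, windows = win, profiles = A,
       dataset = labeled_dataset(site_ids, labels, network$target_name))
}

#' Cross-validated AUC over a grid of signal strengths
#'
#' For each `(match_prob, co_occurrence_prob)` pair, generates a
#' dataset and runs cross-validation under three kernel
#' configurations — sequence kernel only (betas 1, 0), GIP kernel only
#' (0, 1) and the combined kernel (0.5, 0.5) — reporting the averaged
#' AUC of each.
#'
#' @param strengths List of two-element vectors
#'   `c(match_prob, co_occurrence_prob)`.
#' @param n Total samples per dataset (split evenly between classes).
#' @param seed Integer seed.
#' @param folds,repeats Cross-validation settings (defaults 10 and 1).
#' @param network Base [network_spec()]; its `co_occurrence_prob` is
#'   overridden per strength.
#' @param motif_target Target residue for the motif.
#' @param gamma GIP bandwidth.
#' @return A data.frame with columns `match_prob`, `co_occurrence_prob`,
#'   `kernel`, `auc`.
#' @export
signal_sweep <- function(strengths, n, seed = 1L, folds = 10L,
                         repeats = 1L, network = network_spec(),
                         motif_target = "S", gamma = 0.001) {
  if (length(strengths) == 0L) stop_validation("strengths must be non-empty")
  configs <- list(sequence = c(seq = 1, gip = 0),
                  gip = c(seq = 0, gip = 1),
                  combined = c(seq = 0.5, gip = 0.5))
  rows <- list()
  for (s in strengths) {
    mot <- motif_spec(motif_target, match_prob = s[[1L]])
    net <- network
    net$co_occurrence_prob <- max(s[[2L]], net$background_prob)
    dat <- generate_dataset(ceiling(n / 2), floor(n / 2), mot, net, seed)
    for (cf in names(configs)) {
      cv <- run_cv(dat$windows, dat$profiles, dat$dataset,
                   kernel_config(gamma = gamma, betas = configs[[cf]]),
                   model_params(), folds = folds, repeats = repeats,
                   seed = seed)
      rows[[length(rows) + 1L]] <- data.frame(
        match_prob = s[[1L]], co_occurrence_prob = s[[2L]],
        kernel = cf, auc = cv$average$AUC, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
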