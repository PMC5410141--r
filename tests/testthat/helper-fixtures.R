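# Shared fixture builders. All randomness is seeded at the call site.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# n random 21-residue windows with a legal central residue
random_windows <- function(n, width = 21L) {
  w <- vapply(seq_len(n), function(i) {
    chars <- sample(AA20, width, replace = TRUE)
    chars[(width + 1L) %/% 2L] <- sample(c("S", "T", "Y"), 1L)
    paste(chars, collapse = "")
  }, character(1))
  names(w) <- sprintf("P%03d:11", seq_len(n))
  w
}

random_profiles <- function(n, n_ptms = 6L, p = 0.4) {
  A <- matrix(as.integer(runif(n * n_ptms) < p), n, n_ptms,
              dimnames = list(sprintf("P%03d:11", seq_len(n)),
                              c("target", paste0("ptm", seq_len(n_ptms - 1L)))))
  A
}

# Drop the bookkeeping attributes a kernel matrix carries so plain
# numeric comparisons see only the values.
strip_kind <- function(K) {
  attr(K, "kind") <- NULL
  unname(K)
}

# Brute-force positionwise BLOSUM62 similarity (the independent oracle)
brute_seq_similarity <- function(windows) {
  n <- length(windows)
  S <- matrix(0, n, n, dimnames = list(names(windows), names(windows)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      a <- strsplit(windows[[i]], "")[[1]]
      b <- strsplit(windows[[j]], "")[[1]]
      S[i, j] <- sum(vapply(seq_along(a), function(x)
        blosum62_score(a[x], b[x]), numeric(1)))
    }
  }
  S
}

# O(n^2) Mann-Whitney concordance with ties counted one half
brute_concordance_auc <- function(scores, labels) {
  sp <- scores[labels > 0]
  sn <- scores[labels < 0]
  tot <- 0
  for (a in sp) for (b in sn) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(sp) * length(sn))
}

# small FASTA + site table pair on disk; returns the two paths
write_toy_inputs <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  fa <- file.path(dir, "toy.fasta")
  writeLines(c(">P1 first protein", "MKSTYAAKRSTPLM",
               ">P2", "SSSSSSSSSSSSSSSSSSSSS"), fa)
  st <- file.path(dir, "toy_sites.tsv")
  writeLines(c("protein_id\tposition\tresidue\tannotations\ttask_label",
               "P1\t3\tS\tphos.CMGC;OGlcNAc\t+1",
               "P1\t5\tY\t\t-1",
               "P2\t11\tS\tphos.CMGC\t+1"), st)
  list(fasta = fa, sites = st, dir = dir)
}

strong_motif <- function(residue = "S") motif_spec(residue, match_prob = 0.9)
strong_network <- function() network_spec(n_ptms = 5L, co_occurrence_prob = 0.6,
                                          background_prob = 0.05)
null_motif <- function(residue = "S") motif_spec(residue, match_prob = 0)
null_network <- function() network_spec(n_ptms = 5L, co_occurrence_prob = 0.05,
                                        background_prob = 0.05)
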