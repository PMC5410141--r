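# Peptide windows and substitution scores.
#
# A candidate site is represented by its 21-residue local sequence: ten
# residues upstream, the central S/T/Y, ten residues downstream. Windows
# that run past a protein terminus are padded with 'X' so that every
# window has the same length and every position can be scored with the
# extended BLOSUM62 alphabet.

# 20 standard residues plus the ambiguity codes carried by BLOSUM62.
# 'X' doubles as the terminal pad symbol.
AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA_SUPPORTED <- c(AA_STANDARD, "B", "Z", "X")

PAD_SYMBOL <- "X"

#' Condition signal for invalid user input
#'
#' All input-validation failures in the package raise a condition of class
#' `ptmkernels_validation_error` (a subclass of `error`), so callers such
#' as the command-line wrapper can distinguish bad input (exit status 2)
#' from runtime failure (exit status 1).
#'
#' @param ... Message parts, pasted together.
#' @return Does not return; signals an error.
#' @keywords internal
stop_validation <- function(...) {
  msg <- paste0(...)
  stop(structure(
    class = c("ptmkernels_validation_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Read protein sequences from a FASTA file
#'
#' Wraps [Biostrings::readAAStringSet()] with the validation this package
#' needs: the identifier is the header token before the first whitespace,
#' identifiers must be unique, sequences are uppercased, and the
#' selenocysteine/pyrrolysine codes `U`/`O` (absent from BLOSUM62) are
#' mapped to the ambiguity code `X`.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id` and `sequence`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1 demo", "MKSTY"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop_validation("FASTA file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    return(data.frame(id = character(), sequence = character(),
                      stringsAsFactors = FALSE))
  }
  if (!startsWith(trimws(lines[nonblank[1L]]), ">")) {
    stop_validation("malformed FASTA in ", path, ": line ", nonblank[1L],
                    " is not a header line")
  }
  aa <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop_validation("duplicate FASTA ids: ", paste(dup, collapse = ", "))
  }
  seqs <- toupper(as.character(aa))
  seqs <- gsub("[UO]", "X", seqs)
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop_validation("empty sequence for id(s): ",
                    paste(ids[empty], collapse = ", "))
  }
  data.frame(id = unname(ids), sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Read and validate a site annotation table
#'
#' The site table is a TSV with header
#' `protein_id  position  residue  annotations  task_label`.
#' `annotations` is a semicolon-separated list of PTM or kinase-group
#' names the site is experimentally known to carry (may be empty);
#' `task_label` is `+1`/`-1` for the modification under prediction, or
#' empty for an unlabeled candidate site. Every row is validated against
#' the protein collection: the protein must exist, the 1-based position
#' must be in range, and the stated residue must match the sequence.
#'
#' @param path Path to the TSV file.
#' @param proteins A data.frame as returned by [read_fasta()].
#' @return A data.frame with columns `site_id` (`protein_id:position`),
#'   `protein_id`, `position`, `residue`, `annotations` (list column of
#'   character vectors) and `task_label` (integer, `NA` for unlabeled).
#' @export
read_site_table <- function(path, proteins) {
  if (!file.exists(path)) {
    stop_validation("site table not found: ", path)
  }
  tab <- utils::read.delim(path, colClasses = "character",
                           stringsAsFactors = FALSE)
  needed <- c("protein_id", "position", "residue", "annotations", "task_label")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols) > 0L) {
    stop_validation("site table ", path, " lacks column(s): ",
                    paste(missing_cols, collapse = ", "))
  }
  seq_by_id <- stats::setNames(proteins$sequence, proteins$id)
  unknown <- setdiff(unique(tab$protein_id), names(seq_by_id))
  if (length(unknown) > 0L) {
    stop_validation("site table references unknown protein id(s): ",
                    paste(unknown, collapse = ", "))
  }
  pos <- suppressWarnings(as.integer(tab$position))
  bad <- is.na(pos) | pos < 1L | pos > nchar(seq_by_id[tab$protein_id])
  actual <- substr(seq_by_id[tab$protein_id], pos, pos)
  mism <- !bad & actual != toupper(tab$residue)
  if (any(bad) | any(mism)) {
    rows <- which(bad | mism) + 1L  # +1 for the header line
    stop_validation("invalid site rows (position out of range or residue ",
                    "mismatch) at file line(s): ", paste(rows, collapse = ", "))
  }
  ann <- strsplit(tab$annotations, ";", fixed = TRUE)
  ann <- lapply(ann, function(a) unique(a[nzchar(trimws(a))]))
  lab <- suppressWarnings(as.integer(gsub("^\\+", "", trimws(tab$task_label))))
  badlab <- !is.na(lab) & !(lab %in% c(-1L, 1L))
  if (any(badlab)) {
    stop_validation("task_label must be +1, -1 or empty; offending line(s): ",
                    paste(which(badlab) + 1L, collapse = ", "))
  }
  data.frame(
    site_id = paste0(tab$protein_id, ":", pos),
    protein_id = tab$protein_id,
    position = pos,
    residue = toupper(tab$residue),
    annotations = I(ann),
    task_label = lab,
    stringsAsFactors = FALSE
  )
}

#' Extract a fixed-width peptide window around a site
#'
#' Returns the `2 * flank + 1` residues centred on `position`; positions
#' that fall outside the protein are filled with the pad symbol `X`.
#'
#' @param sequence Protein sequence (single string).
#' @param position 1-based position of the central residue.
#' @param flank Number of residues on each side of the centre (default 10,
#'   giving the 21-residue window used throughout the package).
#' @param central_residues Allowed central residues; the default restricts
#'   windows to the S/T/Y sites this predictor targets.
#' @return A single string of length `2 * flank + 1`.
#' @examples
#' extract_window("MKSTY", 3)
#' @export
extract_window <- function(sequence, position, flank = 10L,
                           central_residues = c("S", "T", "Y")) {
  if (flank < 0L) stop_validation("flank must be non-negative")
  len <- nchar(sequence)
  if (position < 1L || position > len) {
    stop_validation("position ", position, " outside sequence of length ", len)
  }
  centre <- substr(sequence, position, position)
  if (!is.null(central_residues) && !(centre %in% central_residues)) {
    stop_validation("central residue at position ", position, " is '", centre,
                    "', expected one of ",
                    paste(central_residues, collapse = "/"))
  }
  lo <- position - flank
  hi <- position + flank
  core <- substr(sequence, max(lo, 1L), min(hi, len))
  left <- strrep(PAD_SYMBOL, max(0L, 1L - lo))
  right <- strrep(PAD_SYMBOL, max(0L, hi - len))
  paste0(left, core, right)
}

#' Extract windows for every row of a site table
#'
#' @param proteins A data.frame from [read_fasta()].
#' @param sites A data.frame from [read_site_table()].
#' @param flank Flank width (default 10).
#' @return A named character vector of windows, names = `site_id`.
#' @export
build_windows <- function(proteins, sites, flank = 10L) {
  seq_by_id <- stats::setNames(proteins$sequence, proteins$id)
  w <- mapply(function(p, pos) extract_window(seq_by_id[[p]], pos, flank),
              sites$protein_id, sites$position)
  stats::setNames(as.character(w), sites$site_id)
}

.blosum_env <- new.env(parent = emptyenv())

#' The embedded BLOSUM62 substitution matrix
#'
#' Parses the canonical NCBI-format BLOSUM62 table shipped with the
#' package (20 standard residues plus B, Z, X and the stop symbol `*`)
#' and caches it. Scores are in half-bit units; `X` scores are the usual
#' least-informative extension (X-X = -1), which also covers terminal
#' pads.
#'
#' @return An integer matrix with row/column names over the supported
#'   symbols.
#' @export
blosum62_matrix <- function() {
  if (is.null(.blosum_env$B)) {
    path <- system.file("extdata", "BLOSUM62.txt", package = "ptmkernels",
                        mustWork = TRUE)
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#")]
    syms <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
    rows <- strsplit(trimws(lines[-1L]), "\\s+")
    B <- t(vapply(rows, function(r) as.integer(r[-1L]),
                  integer(length(syms))))
    dimnames(B) <- list(vapply(rows, `[`, character(1), 1L), syms)
    stopifnot(identical(rownames(B), colnames(B)), isSymmetric(B))
    .blosum_env$B <- B
  }
  .blosum_env$B
}

#' BLOSUM62 score for a pair of symbols
#'
#' @param a,b Single characters from the supported alphabet
#'   (20 residues, B, Z, X, `*`).
#' @return Integer substitution score.
#' @examples
#' blosum62_score("A", "A")  # 4
#' blosum62_score("W", "W")  # 11
#' @export
blosum62_score <- function(a, b) {
  B <- blosum62_matrix()
  for (s in c(a, b)) {
    if (!(s %in% rownames(B))) {
      stop_validation("symbol '", s, "' not supported by BLOSUM62")
    }
  }
  B[a, b]
}

# Encode windows as an m x w integer matrix of alphabet indices into
# blosum62_matrix(); unsupported letters are mapped to 'X'.
encode_windows <- function(windows) {
  if (length(windows) == 0L) {
    stop_validation("no windows to encode")
  }
  w <- unique(nchar(windows))
  if (length(w) != 1L) {
    stop_validation("windows have mixed lengths: ",
                    paste(w, collapse = ", "))
  }
  B <- blosum62_matrix()
  chars <- matrix(unlist(strsplit(windows, "")), nrow = length(windows),
                  byrow = TRUE)
  idx <- match(chars, rownames(B))
  idx[is.na(idx)] <- match(PAD_SYMBOL, rownames(B))
  enc <- matrix(idx, nrow = length(windows))
  rownames(enc) <- names(windows)
  enc
}
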