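#' Construct a multiple sequence alignment object
#'
#' Holds aligned sequences over a finite state alphabet (by default the 20
#' amino acids plus the gap character), the row index of the query/reference
#' sequence, and the map from alignment columns to reference positions
#' (non-gap query columns are numbered consecutively from `first_position`).
#'
#' @param sequences Character vector of aligned sequences (equal lengths),
#'   or a character matrix with one row per sequence.
#' @param query_index Row index of the reference sequence (default 1).
#' @param alphabet State alphabet; defaults to the 20 amino acids plus
#'   `"-"`. Supply a smaller alphabet for toy models.
#' @param first_position Reference position of the first non-gap query
#'   column (default 1).
#' @return An object of class `msa`: a list with `states` (integer matrix,
#'   n x L, values indexing `alphabet`), `alphabet`, `query_index`,
#'   `column_map` (reference position per column, `NA` at query gaps).
#' @export
msa <- function(sequences, query_index = 1L, alphabet = NULL,
                first_position = 1L) {
  if (is.matrix(sequences)) {
    chars <- sequences
  } else {
    if (length(unique(nchar(sequences))) != 1L) {
      abort("aligned sequences must all have the same length")
    }
    chars <- do.call(rbind, strsplit(toupper(sequences), ""))
  }
  alphabet <- alphabet %||% c(AA_ALPHABET, "-")
  states <- matrix(
    match(chars, alphabet),
    nrow = nrow(chars), ncol = ncol(chars)
  )
  if (any(is.na(states))) {
    bad <- unique(chars[is.na(states)])
    abort(paste0("characters outside the alphabet: ", paste(bad, collapse = " ")))
  }
  gap_state <- match("-", alphabet)
  qry <- states[query_index, ]
  is_gap <- if (is.na(gap_state)) rep(FALSE, length(qry)) else qry == gap_state
  column_map <- rep(NA_integer_, length(qry))
  column_map[!is_gap] <- seq.int(first_position, length.out = sum(!is_gap))
  structure(
    list(
      states = states, alphabet = alphabet,
      query_index = query_index, column_map = column_map
    ),
    class = "msa"
  )
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf(
    "MSA: %d sequences x %d columns, %d-state alphabet, query row %d\n",
    nrow(x$states), ncol(x$states), length(x$alphabet), x$query_index
  ))
  invisible(x)
}

#' Read an alignment from FASTA or A2M
#'
#' Plain FASTA alignments are treated as all-match columns. A2M input is
#' collapsed to match columns first: lowercase insert states and `.`
#' padding are removed, and remaining residues upper-cased.
#'
#' @param path Path to a FASTA/A2M file.
#' @param query_index Row index of the reference sequence (default 1).
#' @param first_position Reference numbering of the first query residue.
#' @return An [msa()] object.
#' @export
read_msa <- function(path, query_index = 1L, first_position = 1L) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("reading FASTA alignments requires the Biostrings package")
  }
  set <- Biostrings::readBStringSet(path)
  seqs <- as.character(set)
  # A2M: drop insert states (lowercase and '.')
  seqs <- gsub("[a-z.]", "", seqs)
  msa(seqs, query_index = query_index, first_position = first_position)
}

#' Identity-based sequence weights
#'
#' Down-weights redundant alignment rows: each sequence gets weight
#' 1 / (number of sequences, itself included, with fractional identity >=
#' `theta`). Identity is computed over all columns, gaps included. The sum
#' of weights is the effective number of sequences, Meff.
#'
#' @param aln An [msa()] object.
#' @param theta Identity threshold as a fraction (default 0.8).
#' @return A list of class `seq_weights`: `weights`, `theta`, `m_eff`.
#' @export
compute_weights <- function(aln, theta = 0.8) {
  stopifnot(inherits(aln, "msa"))
  X <- aln$states
  n <- nrow(X)
  L <- ncol(X)
  if (n < 2) abort("need at least 2 sequences to compute weights")
  matches <- matrix(0, n, n)
  for (j in seq_len(L)) {
    matches <- matches + outer(X[, j], X[, j], "==")
  }
  neighbours <- rowSums(matches / L >= theta)
  w <- 1 / neighbours
  structure(
    list(weights = w, theta = theta, m_eff = sum(w)),
    class = "seq_weights"
  )
}

#' Uniform sequence weights
#'
#' All sequences weighted 1 (Meff = n). Appropriate when rows are
#' independent draws — e.g. synthetic alignments sampled from a known
#' model — where identity-based down-weighting would only add noise;
#' identity reweighting exists to correct phylogenetic redundancy.
#'
#' @param aln An [msa()] object (or an integer number of sequences).
#' @return A `seq_weights` object with unit weights.
#' @export
uniform_weights <- function(aln) {
  n <- if (inherits(aln, "msa")) nrow(aln$states) else as.integer(aln)
  structure(
    list(weights = rep(1, n), theta = NA_real_, m_eff = n),
    class = "seq_weights"
  )
}

#' @export
print.seq_weights <- function(x, ...) {
  cat(sprintf(
    "%d sequence weights at theta = %.2f; Meff = %.2f\n",
    length(x$weights), x$theta, x$m_eff
  ))
  invisible(x)
}
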