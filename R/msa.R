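# Deterministic progressive multiple alignment: sequences are added one at
# a time to a growing profile with an affine-gap Gotoh alignment against
# mean BLOSUM62 column scores. For two sequences this reduces to ordinary
# global pairwise alignment.

#' Construct a `pep_msa` from pre-aligned rows
#' @param seqs equal-length gapped sequences.
#' @param pep_ids optional row ids.
#' @return a `pep_msa`.
#' @export
new_msa <- function(seqs, pep_ids = NULL) {
  pep_ids <- pep_ids %||% paste0("seq", seq_along(seqs))
  stopifnot(length(unique(nchar(seqs))) <= 1L)
  structure(list(seqs = seqs, pep_ids = pep_ids), class = "pep_msa")
}

# mean substitution score of each alignment column against each residue;
# gap rows contribute 0
msa_column_scores <- function(rows_mat, b62) {
  n <- nrow(rows_mat)
  letters21 <- c(AA20, "X")
  # counts: K x 21 occurrence matrix, then one matrix product
  counts <- vapply(letters21, function(a) colSums(rows_mat == a),
                   numeric(ncol(rows_mat)))
  if (ncol(rows_mat) == 1L) counts <- matrix(counts, nrow = 1L)
  (counts %*% b62[letters21, letters21]) / n
}

#' Build a multiple sequence alignment
#'
#' Deterministic progressive alignment in input order. Identical inputs
#' always produce identical output; ungapping row *i* reproduces input
#' sequence *i*.
#'
#' @param sequences character vector of peptides (length >= 1).
#' @param pep_ids optional sequence ids.
#' @param config a [pipeline_config()] supplying gap penalties.
#' @return a `pep_msa`: list with equal-length gapped `seqs` and `pep_ids`.
#' @export
build_msa <- function(sequences, pep_ids = NULL,
                      config = pipeline_config()) {
  if (length(sequences) == 0L) stopf("build_msa: empty input set")
  if (any(nchar(sequences) == 0L)) stopf("build_msa: empty sequence")
  if (length(sequences) == 1L) return(new_msa(sequences, pep_ids))
  b62 <- b62_matrix()
  rows <- strsplit(sequences[1], "", fixed = TRUE)
  rows_mat <- matrix(rows[[1]], nrow = 1L)
  for (i in 2:length(sequences)) {
    colsc <- msa_column_scores(rows_mat, b62)
    qi <- aa_index0(sequences[i])
    qi[qi < 0L] <- 20L  # X column of the 21-letter score matrix
    al <- align_profile_seq_cpp(colsc, qi, config$gap_open, config$gap_ext)
    ops <- al$ops
    K <- ncol(rows_mat)
    newK <- length(ops)
    out <- matrix("-", nrow = nrow(rows_mat) + 1L, ncol = newK)
    qchars <- split1(sequences[i])
    k <- 0L; j <- 0L
    for (t in seq_len(newK)) {
      op <- ops[t]
      if (op == 1L) {            # column + residue
        k <- k + 1L; j <- j + 1L
        out[-nrow(out), t] <- rows_mat[, k]
        out[nrow(out), t] <- qchars[j]
      } else if (op == 2L) {     # column against gap in new sequence
        k <- k + 1L
        out[-nrow(out), t] <- rows_mat[, k]
      } else {                   # new residue, all-gap column for old rows
        j <- j + 1L
        out[nrow(out), t] <- qchars[j]
      }
    }
    rows_mat <- out
  }
  new_msa(apply(rows_mat, 1L, paste, collapse = ""), pep_ids)
}
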