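# Profile models: match-state emission scores built from a multiple
# alignment, the consensus sequence, the maximum attainable score, and
# Viterbi scoring of queries with the consensus-normalized relative score R.

#' Build a profile model from a multiple alignment
#'
#' Alignment columns whose non-gap occupancy is at least the occupancy
#' threshold (default 0.5, inclusive) become match states. Emission
#' probabilities use a pseudocount: `e_k(a) = (c_k(a) + alpha*q_a) /
#' (n_k + alpha)` with total pseudocount mass `alpha` (default 1) and a
#' uniform background `q_a = 1/20`; match scores are the log-odds
#' `m_k(a) = log2(e_k(a)/q_a)` in bits. Every row is weighted fully
#' (no fragment down-weighting, no sequence weighting). `X` residues count
#' toward occupancy but contribute no emission count.
#'
#' @param msa a `pep_msa` from [build_msa()].
#' @param config a [pipeline_config()] (occupancy threshold, pseudocount,
#'   penalties).
#' @return a `profile_model`: list with `match` (K x 20 bit-score matrix),
#'   `consensus`, `max_score`, `column_map`, `penalties`.
#' @export
build_profile <- function(msa, config = pipeline_config()) {
  rows <- strsplit(msa$seqs, "", fixed = TRUE)
  mat <- do.call(rbind, rows)
  n <- nrow(mat)
  occ <- colMeans(mat != "-")
  match_cols <- which(occ >= config$occupancy_threshold)
  if (length(match_cols) == 0L)
    stopf("build_profile: alignment has no match columns")
  alpha <- config$pseudocount
  q <- 1 / 20
  sub <- mat[, match_cols, drop = FALSE]
  counts <- vapply(AA20, function(a) colSums(sub == a),
                   numeric(length(match_cols)))
  if (length(match_cols) == 1L) counts <- matrix(counts, nrow = 1L)
  nk <- rowSums(counts)
  e <- (counts + alpha * q) / (nk + alpha)   # recycles nk down the rows
  m <- log2(e / q)
  dimnames(m) <- list(NULL, AA20)
  cons <- AA20[max.col(e, ties.method = "first")]  # first = alphabetical
  max_score <- sum(apply(m, 1L, max))
  if (max_score < 1)
    stopf("build_profile: degenerate profile (max_score = %.3f bits)",
          max_score)
  structure(list(match = m,
                 consensus = paste(cons, collapse = ""),
                 max_score = max_score,
                 column_map = match_cols,
                 penalties = config$penalties),
            class = "profile_model")
}

#' Consensus sequence of a profile
#'
#' One residue per match state: the residue maximizing the emission
#' probability, ties broken alphabetically. Rescoring the consensus against
#' its own profile gives R exactly 1.
#'
#' @param profile a `profile_model`.
#' @return the consensus peptide string.
#' @export
profile_consensus <- function(profile) profile$consensus

#' Score a sequence against a profile
#'
#' Best-path (Viterbi) score, global in both the profile and the query:
#' every match state is matched or deleted (delete penalty per state), and
#' every query residue is matched or inserted (affine insert penalties,
#' zero insert emission). The relative score is `R = raw / max_score`,
#' where `max_score` is the score of the profile consensus, so `R <= 1`
#' always and `R = 1` for the consensus itself.
#'
#' @param profile a `profile_model`.
#' @param seq a peptide string (non-empty).
#' @return a `profile_score`: list with `raw` (bits) and `R`.
#' @export
score_profile <- function(profile, seq) {
  if (nchar(seq) == 0L) stopf("score_profile: empty sequence")
  q <- aa_index0(seq)
  p <- profile$penalties
  raw <- viterbi_raw_cpp(profile$match, q,
                         p[["delete"]], p[["insert_open"]],
                         p[["insert_extend"]])
  structure(list(raw = raw, R = raw / profile$max_score),
            class = "profile_score")
}

# vectorized raw scores (bits) for many sequences against one profile
profile_raw_many <- function(profile, seqs) {
  if (length(seqs) == 0L) return(numeric(0))
  p <- profile$penalties
  viterbi_raw_batch_cpp(profile$match, lapply(seqs, aa_index0),
                        p[["delete"]], p[["insert_open"]],
                        p[["insert_extend"]])
}

# vectorized convenience: R values for many sequences
score_profile_many <- function(profile, seqs) {
  profile_raw_many(profile, seqs) / profile$max_score
}

#' Raw-score hit gate
#'
#' The internal analogue of an E-value threshold: a scored query passes iff
#' its raw bit score reaches `min_raw_bits` (inclusive).
#'
#' @param score a `profile_score` from [score_profile()].
#' @param config a [pipeline_config()].
#' @return logical.
#' @export
hit_filter <- function(score, config = pipeline_config()) {
  score$raw >= config$min_raw_bits
}

#' Serialize a profile model to a plain-text table
#'
#' One row per match state: the consensus residue followed by the 20 match
#' scores in bits. Penalties and the source column map are stored in
#' comment headers so [read_profile()] can reconstruct the model.
#'
#' @param profile a `profile_model`.
#' @param path output path.
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  p <- profile$penalties
  writeLines(c(
    sprintf("# univgroups profile"),
    sprintf("# penalties\tdelete=%.6g\tinsert_open=%.6g\tinsert_extend=%.6g",
            p[["delete"]], p[["insert_open"]], p[["insert_extend"]]),
    sprintf("# max_score\t%.10g", profile$max_score),
    sprintf("# column_map\t%s", paste(profile$column_map, collapse = ",")),
    paste(c("state", "consensus", AA20), collapse = "\t")), con)
  cons <- split1(profile$consensus)
  for (k in seq_len(nrow(profile$match))) {
    writeLines(paste(c(k, cons[k],
                       sprintf("%.10g", profile$match[k, ])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a profile model written by [write_profile()]
#' @param path profile file path.
#' @return a `profile_model`.
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  pen_line <- hdr[grepl("penalties", hdr)]
  pv <- regmatches(pen_line,
                   gregexpr("[a-z_]+=[-0-9.eE+]+", pen_line))[[1]]
  kv <- do.call(rbind, strsplit(pv, "=", fixed = TRUE))
  penalties <- stats::setNames(as.numeric(kv[, 2]), kv[, 1])
  cmap_line <- hdr[grepl("column_map", hdr)]
  column_map <- as.integer(strsplit(sub("^.*\t", "", cmap_line),
                                    ",")[[1]])
  body <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                            stringsAsFactors = FALSE)
  m <- as.matrix(body[, AA20])
  dimnames(m) <- list(NULL, AA20)
  structure(list(match = m,
                 consensus = paste(body$consensus, collapse = ""),
                 max_score = sum(apply(m, 1L, max)),
                 column_map = column_map,
                 penalties = penalties),
            class = "profile_model")
}
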