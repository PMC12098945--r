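# Independent oracles used to freeze expected values. These deliberately
# re-derive scores by brute force, never through the code paths they check.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# exhaustive path enumeration of the profile alignment score: every match
# state is matched or deleted, every residue matched or inserted; an insert
# run costs open for its first residue and ext for each later one
enum_align_score <- function(m, qidx, del, open, ext) {
  K <- nrow(m); L <- length(qidx)
  emit <- function(k, j) if (qidx[j] < 0) 0 else m[k, qidx[j] + 1L]
  rec <- function(k, j, last_ins) {
    if (k == K && j == L) return(0)
    best <- -Inf
    if (k < K && j < L)
      best <- max(best, emit(k + 1L, j + 1L) + rec(k + 1L, j + 1L, FALSE))
    if (k < K)
      best <- max(best, -del + rec(k + 1L, j, FALSE))
    if (j < L)
      best <- max(best, (if (last_ins) -ext else -open) +
                    rec(k, j + 1L, TRUE))
    best
  }
  rec(0L, 0L, FALSE)
}

# brute-force global affine pairwise alignment score with the package's
# cost convention (gap of length g costs open + (g-1)*ext), enumerating
# all alignments of two short strings
enum_pairwise_score <- function(a, b, sub, open, ext) {
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  rec <- function(i, j, last) {
    if (i > length(ac) && j > length(bc)) return(0)
    best <- -Inf
    if (i <= length(ac) && j <= length(bc))
      best <- max(best, sub[ac[i], bc[j]] + rec(i + 1L, j + 1L, "M"))
    if (i <= length(ac))
      best <- max(best, (if (last == "A") -ext else -open) +
                    rec(i + 1L, j, "A"))
    if (j <= length(bc))
      best <- max(best, (if (last == "B") -ext else -open) +
                    rec(i, j + 1L, "B"))
    best
  }
  rec(1L, 1L, "M")
}

rand_seq <- function(len, letters = AA) {
  paste(sample(letters, len, replace = TRUE), collapse = "")
}

# a random small profile built from a random ungapped MSA
rand_profile <- function(n_rows = 4, len = 12, config = pipeline_config()) {
  anc <- rand_seq(len)
  rows <- vapply(seq_len(n_rows), function(i) {
    ch <- strsplit(anc, "")[[1]]
    mut <- runif(length(ch)) < 0.15
    ch[mut] <- sample(AA, sum(mut), replace = TRUE)
    paste(ch, collapse = "")
  }, "")
  build_profile(build_msa(rows, config = config), config)
}

aa_idx <- function(seq) {
  idx <- match(strsplit(seq, "")[[1]], AA)
  idx[is.na(idx)] <- 0L
  idx - 1L
}

# deterministic back-translation (first codon of each residue) + a spacer
# with stop codons in all six frames, for building tiny genomes
.codon <- local({
  b <- c("T", "C", "A", "G")
  cods <- as.vector(outer(outer(b, b, paste0), b, paste0))
  aa <- vapply(cods, function(cd)
    as.character(Biostrings::translate(Biostrings::DNAString(cd),
                                       no.init.codon = TRUE)), "")
  split(cods, aa)
})

bt <- function(pep) {
  paste0(paste(vapply(strsplit(pep, "")[[1]],
                      function(a) .codon[[a]][1], ""), collapse = ""),
         "TAA")
}

spacer <- paste(rep("TTAATTAATTAA", 8), collapse = "")

# tiny in-memory pep_db builder
mini_db <- function(...) {
  rows <- list(...)
  db <- do.call(rbind, lapply(rows, function(r)
    data.frame(pep_id = r[[1]], gene_id = r[[2]], species = r[[3]],
               sequence = r[[4]],
               source = if (length(r) > 4) r[[5]] else "annotated",
               stringsAsFactors = FALSE)))
  rownames(db) <- db$pep_id
  class(db) <- c("pep_db", "data.frame")
  db
}

# build a ready-made universal group from named member sequences
mk_universal_group <- function(id, member_seqs, db,
                               config = pipeline_config()) {
  sp <- names(member_seqs)
  g <- list(group_id = id,
            members = as.list(stats::setNames(
              db$pep_id[match(member_seqs, db$sequence)], sp)),
            member_R = list(), n_rescued = 0L,
            status = "universal", reason = NA_character_,
            msa = NULL, profile = NULL)
  g$msa <- build_msa(unname(member_seqs), unlist(g$members), config)
  g$profile <- build_profile(g$msa, config)
  g$member_R <- lapply(g$members, function(i)
    score_profile(g$profile, db$sequence[match(i, db$pep_id)])$R)
  g
}
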