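# Pairwise global identity and near-identity clustering of reference
# peptides.

#' Bidirectional global percent identity
#'
#' Globally aligns two peptides (BLOSUM62, affine gaps, blastp-default
#' penalties) and reports percent identity in both directions: the number of
#' identically aligned residue pairs divided by each sequence's own
#' ungapped length. Both directions share the numerator.
#'
#' @param a,b peptide strings (non-empty).
#' @param config a [pipeline_config()] supplying gap penalties.
#' @return a list with `pct_ab`, `pct_ba`, `matches` and `aln_length`.
#' @export
global_identity <- function(a, b, config = pipeline_config()) {
  if (nchar(a) == 0L || nchar(b) == 0L)
    stopf("global_identity: empty sequence")
  b62 <- b62_matrix()
  achars <- split1(toupper(a))
  rowsel <- ifelse(achars %in% AA20, achars, "X")
  colsc <- b62[rowsel, , drop = FALSE]
  qi <- aa_index0(toupper(b))
  qi[qi < 0L] <- 20L
  al <- align_profile_seq_cpp(colsc, qi, config$gap_open, config$gap_ext)
  bchars <- split1(toupper(b))
  ai <- 0L; bi <- 0L; matches <- 0L
  for (op in al$ops) {
    if (op == 1L) {
      ai <- ai + 1L; bi <- bi + 1L
      if (achars[ai] == bchars[bi]) matches <- matches + 1L
    } else if (op == 2L) ai <- ai + 1L else bi <- bi + 1L
  }
  list(pct_ab = 100 * matches / nchar(a),
       pct_ba = 100 * matches / nchar(b),
       matches = matches,
       aln_length = length(al$ops),
       score = al$score)
}

# do two sequences share any k-mer? (alignment-free screen)
shares_kmer <- function(a, b, k = 4L) {
  if (nchar(a) < k || nchar(b) < k) return(TRUE)  # too short to screen
  ka <- substring(a, seq_len(nchar(a) - k + 1L), seq(k, nchar(a)))
  kb <- substring(b, seq_len(nchar(b) - k + 1L), seq(k, nchar(b)))
  any(ka %in% kb)
}

#' Collapse reference peptides into near-identity clusters
#'
#' Greedy complete-linkage clustering in input order: a peptide joins the
#' first existing cluster for which every pairwise comparison clears the
#' bidirectional identity threshold (strict `>`), otherwise it starts a new
#' cluster. A 4-mer pre-screen skips alignments for pairs that cannot be
#' near-identical; it is behaviour-neutral at the default 90% threshold.
#'
#' @param peps a `species_pep_set` from one (deduplicated) reference
#'   species.
#' @param threshold_pct identity threshold in percent (strict, both
#'   directions).
#' @param config a [pipeline_config()].
#' @param prefix cluster id prefix.
#' @return data.frame with columns `pep_id`, `cluster_id`; cluster ids are
#'   assigned in order of first appearance.
#' @export
collapse_reference_clusters <- function(peps,
                                        threshold_pct = NULL,
                                        config = pipeline_config(),
                                        prefix = "C") {
  threshold_pct <- threshold_pct %||% config$cluster_identity_pct
  n <- nrow(peps)
  cluster_of <- integer(n)
  clusters <- list()  # each: integer vector of row indices
  for (i in seq_len(n)) {
    placed <- FALSE
    for (ci in seq_along(clusters)) {
      ok <- TRUE
      for (j in clusters[[ci]]) {
        if (!shares_kmer(peps$sequence[i], peps$sequence[j])) {
          ok <- FALSE; break
        }
        id <- global_identity(peps$sequence[i], peps$sequence[j], config)
        if (!(id$pct_ab > threshold_pct && id$pct_ba > threshold_pct)) {
          ok <- FALSE; break
        }
      }
      if (ok) {
        clusters[[ci]] <- c(clusters[[ci]], i)
        cluster_of[i] <- ci
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      clusters[[length(clusters) + 1L]] <- i
      cluster_of[i] <- length(clusters)
    }
  }
  data.frame(pep_id = peps$pep_id,
             cluster_id = sprintf("%s%04d", prefix, cluster_of),
             stringsAsFactors = FALSE)
}
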