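# Post-pipeline scans: associate-peptide assignment, supergroup detection,
# and validation matching of external proteomes and genomes.

#' Assign associate peptides to groups
#'
#' Every (peptide, group) pair with R above `r_min` (strict), passing the
#' raw-score hit gate, where the peptide is not a member of that group, is
#' recorded; many-to-many relationships are allowed.
#'
#' @param gs finalized `group_set`.
#' @param all_peps a `pep_db` of ingroup peptides.
#' @param config a [pipeline_config()].
#' @return data.frame: `pep_id`, `species`, `group_id`, `R`.
#' @export
assign_associates <- function(gs, all_peps, config = pipeline_config()) {
  out <- list()
  for (g in universal_groups(gs)) {
    members <- unlist(g$members, use.names = FALSE)
    pool <- all_peps[!(all_peps$pep_id %in% members), , drop = FALSE]
    if (nrow(pool) == 0L) next
    raw <- profile_raw_many(g$profile, pool$sequence)
    R <- raw / g$profile$max_score
    keep <- raw >= config$min_raw_bits & R > config$r_min
    if (!any(keep)) next
    out[[length(out) + 1L]] <- data.frame(
      pep_id = pool$pep_id[keep], species = pool$species[keep],
      group_id = g$group_id, R = R[keep], stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(pep_id = character(), species = character(),
               group_id = character(), R = numeric(),
               stringsAsFactors = FALSE)
  res[order(res$group_id, res$pep_id), , drop = FALSE]
}

# does every member of group a score R > r_min against profile of group b?
all_members_hit <- function(ga, gb, pep_db, config) {
  seqs <- pep_seq(pep_db, unlist(ga$members, use.names = FALSE))
  raw <- profile_raw_many(gb$profile, seqs)
  R <- raw / gb$profile$max_score
  all(raw >= config$min_raw_bits & R > config$r_min)
}

#' Detect supergroups of potentially same function
#'
#' Two groups are linked iff every member of each scores R above `r_min`
#' against the other's profile (mutual all-member hits). Supergroups are
#' the connected components of this relation with at least two groups
#' (`supergroup_mode = "components"`, default) or greedy maximal cliques
#' (`"clique"`).
#'
#' @param gs finalized `group_set`.
#' @param pep_db peptide database.
#' @param config a [pipeline_config()].
#' @return list of character vectors of group ids (each sorted), sorted by
#'   first member; empty list if none.
#' @export
find_supergroups <- function(gs, pep_db, config = pipeline_config()) {
  uni <- universal_groups(gs)
  ids <- sort(names(uni))
  n <- length(ids)
  if (n < 2L) return(list())
  edge <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ga <- uni[[ids[i]]]; gb <- uni[[ids[j]]]
      if (all_members_hit(ga, gb, pep_db, config) &&
          all_members_hit(gb, ga, pep_db, config))
        edge[i, j] <- edge[j, i] <- TRUE
    }
  }
  if (config$supergroup_mode == "clique") {
    comp <- list(); usedv <- logical(n)
    for (i in seq_len(n)) {
      if (usedv[i]) next
      members <- i
      for (j in seq_len(n)) {
        if (j == i || usedv[j]) next
        if (all(edge[j, members])) members <- c(members, j)
      }
      if (length(members) > 1L) {
        usedv[members] <- TRUE
        comp[[length(comp) + 1L]] <- sort(ids[members])
      }
    }
    return(comp)
  }
  # connected components
  comp_id <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (edge[i, j] && comp_id[j] != comp_id[i]) {
        new <- min(comp_id[i], comp_id[j])
        comp_id[c(i, j)] <- new
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comps <- split(ids, comp_id)
  comps <- Filter(function(x) length(x) > 1L, comps)
  comps <- lapply(comps, sort)
  names(comps) <- NULL
  comps[order(vapply(comps, `[`, "", 1L))]
}

#' Match an external proteome against the group profiles
#'
#' Per group, the best R over all external peptides passing the hit gate;
#' a group is matched (supported) iff its best R exceeds `r_min`.
#'
#' @param gs finalized `group_set`.
#' @param external_peps a `species_pep_set`/data.frame of external
#'   peptides.
#' @param config a [pipeline_config()].
#' @return list with `per_group` (data.frame group_id, best_R, matched)
#'   and `matched_fraction`.
#' @export
match_external_proteome <- function(gs, external_peps,
                                    config = pipeline_config()) {
  if (nrow(external_peps) == 0L)
    stopf("match_external_proteome: empty external set")
  uni <- universal_groups(gs)
  rows <- lapply(uni[sort(names(uni))], function(g) {
    raw <- profile_raw_many(g$profile, external_peps$sequence)
    R <- raw[raw >= config$min_raw_bits] / g$profile$max_score
    best <- if (length(R)) max(R) else 0
    data.frame(group_id = g$group_id, best_R = best,
               matched = best > config$r_min, stringsAsFactors = FALSE)
  })
  per_group <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  list(per_group = per_group,
       matched_fraction = mean(per_group$matched))
}

#' Match an unannotated external genome against the group profiles
#'
#' Rescue-style search: six-frame ORF models (or an external adapter) are
#' scored against each group profile; a group is matched iff its best
#' model's R exceeds `r_min`.
#'
#' @param gs finalized `group_set`.
#' @param genome `DNAStringSet`, FASTA path, or [orf_index()] data.frame.
#' @param config a [pipeline_config()].
#' @param adapter optional external adapter.
#' @return list with `per_group` and `matched_fraction`.
#' @export
match_external_genome <- function(gs, genome,
                                  config = pipeline_config(),
                                  adapter = NULL) {
  idx <- if (is.data.frame(genome)) genome else orf_index(genome)
  uni <- universal_groups(gs)
  rows <- lapply(uni[sort(names(uni))], function(g) {
    models <- tryCatch(
      find_candidate_models(idx, g$profile, "external", config, adapter),
      error = function(e) list())
    best <- if (length(models))
      max(vapply(models, `[[`, 0, "R")) else 0
    data.frame(group_id = g$group_id, best_R = best,
               matched = best > config$r_min, stringsAsFactors = FALSE)
  })
  per_group <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  list(per_group = per_group,
       matched_fraction = mean(per_group$matched))
}
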