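# Group building: seed candidate groups from dual reference-species
# ortholog tables, enforce exclusive assignment, prune sparse groups,
# optimize to one member per species by relative score R, and apply the
# universality filter.

#' Combine species peptide sets into one peptide database
#' @param pep_sets list of `species_pep_set` objects.
#' @return a data.frame of class `pep_db` keyed by `pep_id`.
#' @export
build_pep_db <- function(pep_sets) {
  db <- do.call(rbind, lapply(pep_sets, as.data.frame))
  rownames(db) <- db$pep_id
  class(db) <- c("pep_db", "data.frame")
  db
}

pep_seq <- function(pep_db, ids) pep_db$sequence[match(ids, pep_db$pep_id)]

# primary (first-seen) peptide of each gene
primary_peps <- function(pep_db, species) {
  d <- pep_db[pep_db$species == species, ]
  d[!duplicated(d$gene_id), ]
}

# default cross-reference best hit: highest mean bidirectional identity,
# requiring a minimum mean identity to count as "similar"
default_best_hit <- function(config) {
  function(seq, target_peps) {
    best <- NULL; best_sim <- -Inf
    for (i in seq_len(nrow(target_peps))) {
      if (!shares_kmer(seq, target_peps$sequence[i])) next
      id <- global_identity(seq, target_peps$sequence[i], config)
      sim <- (id$pct_ab + id$pct_ba) / 2
      if (sim > best_sim) { best_sim <- sim; best <- target_peps[i, ] }
    }
    if (is.null(best) || best_sim < config$min_seed_identity) return(NULL)
    best
  }
}

#' Seed candidate groups from two reference ortholog tables
#'
#' One group per cluster of the first reference species. The second
#' reference is merged in through its ortholog link; where there is none,
#' the most similar second-reference peptide is found and merged only if it
#' is not orthologous to a different first-reference gene (composite group
#' id). Second-reference clusters with no link of their own seed their own
#' groups. Candidates for every other species are the union of orthologs of
#' both references, expanded to all splice-variant peptides of each target
#' gene, with the Ensembl-style confidence flag and the global identity to
#' the group's reference peptide recorded for ranking.
#'
#' @param ref_tables list of two `ortholog_table`s (with
#'   `reference_species` attributes).
#' @param ref_clusters named list (by reference species) of cluster tables
#'   from [collapse_reference_clusters()] over the primary peptides;
#'   `NULL` computes them.
#' @param all_peps a `pep_db` from [build_pep_db()].
#' @param best_hit_fn function(seq, target_pep_set) -> row or NULL;
#'   `NULL` uses the built-in identity-based best hit.
#' @param config a [pipeline_config()].
#' @return a `group_set`.
#' @export
seed_groups <- function(ref_tables, ref_clusters = NULL, all_peps,
                        best_hit_fn = NULL, config = pipeline_config()) {
  ref1 <- attr(ref_tables[[1]], "reference_species")
  ref2 <- attr(ref_tables[[2]], "reference_species")
  species <- sort(unique(all_peps$species))
  if (!all(c(ref1, ref2) %in% species))
    stopf("reference species %s/%s absent from peptide sets", ref1, ref2)
  best_hit_fn <- best_hit_fn %||% default_best_hit(config)

  prim1 <- primary_peps(all_peps, ref1)
  prim2 <- primary_peps(all_peps, ref2)
  if (is.null(ref_clusters)) {
    ref_clusters <- stats::setNames(list(
      collapse_reference_clusters(prim1, config = config, prefix = "R"),
      collapse_reference_clusters(prim2, config = config, prefix = "M")),
      c(ref1, ref2))
  }
  cl1 <- ref_clusters[[ref1]]; cl2 <- ref_clusters[[ref2]]
  gene_cl1 <- stats::setNames(cl1$cluster_id,
                              prim1$gene_id[match(cl1$pep_id, prim1$pep_id)])
  gene_cl2 <- stats::setNames(cl2$cluster_id,
                              prim2$gene_id[match(cl2$pep_id, prim2$pep_id)])
  genes_of_cl1 <- split(names(gene_cl1), gene_cl1)
  genes_of_cl2 <- split(names(gene_cl2), gene_cl2)

  t1 <- as.data.frame(ref_tables[[1]])
  t2 <- as.data.frame(ref_tables[[2]])

  groups <- list()
  links <- list()
  used_cl2 <- character(0)

  add_links <- function(group_id, sp, genes, conf_of_gene, ref_seq,
                        pepdb) {
    out <- list()
    for (g in genes) {
      peps <- pepdb[pepdb$gene_id == g & pepdb$species == sp, ]
      if (nrow(peps) == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        group_id = group_id, species = sp, pep_id = peps$pep_id,
        gene_id = g, confidence = conf_of_gene[[g]],
        similarity = NA_real_, stringsAsFactors = FALSE)
    }
    out
  }

  seed_one <- function(group_id, genes1, genes2) {
    ref_gene <- if (length(genes1)) genes1[1] else genes2[1]
    ref_sp <- if (length(genes1)) ref1 else ref2
    ref_seq <- all_peps$sequence[
      all_peps$species == ref_sp & all_peps$gene_id == ref_gene][1]
    lk <- list()
    if (length(genes1))
      lk <- c(lk, add_links(group_id, ref1, genes1,
                            stats::setNames(rep(1L, length(genes1)),
                                            genes1),
                            ref_seq, all_peps))
    if (length(genes2))
      lk <- c(lk, add_links(group_id, ref2, genes2,
                            stats::setNames(rep(1L, length(genes2)),
                                            genes2),
                            ref_seq, all_peps))
    rows <- rbind(
      t1[t1$ref_gene %in% genes1 & t1$target_species != ref2, ],
      t2[t2$ref_gene %in% genes2 & t2$target_species != ref1, ])
    for (sp in sort(unique(rows$target_species))) {
      r <- rows[rows$target_species == sp, ]
      conf <- vapply(split(r$confidence, r$target_gene), max, 0L)
      lk <- c(lk, add_links(group_id, sp, sort(unique(r$target_gene)),
                            as.list(conf), ref_seq, all_peps))
    }
    groups[[group_id]] <<- list(
      group_id = group_id, seed_genes = list(genes1, genes2),
      ref_seq = ref_seq,
      members = list(), member_R = list(), n_rescued = 0L,
      status = "seeded", reason = NA_character_,
      msa = NULL, profile = NULL)
    links <<- c(links, lk)
  }

  for (cid in sort(names(genes_of_cl1))) {
    genes1 <- sort(genes_of_cl1[[cid]])
    orth2 <- unique(t1$target_gene[t1$ref_gene %in% genes1 &
                                   t1$target_species == ref2])
    linked_cl2 <- unique(stats::na.omit(gene_cl2[orth2]))
    group_id <- paste0(ref1, ":", cid)
    if (length(linked_cl2) == 0L) {
      # no ortholog: try the most similar second-reference peptide
      ref_seq <- all_peps$sequence[all_peps$species == ref1 &
                                   all_peps$gene_id == genes1[1]][1]
      hit <- best_hit_fn(ref_seq, prim2)
      if (!is.null(hit)) {
        back <- t2$target_gene[t2$ref_gene == hit$gene_id &
                               t2$target_species == ref1]
        if (length(back) == 0L || all(back %in% genes1)) {
          linked_cl2 <- unname(gene_cl2[hit$gene_id])
          linked_cl2 <- linked_cl2[!is.na(linked_cl2)]
          if (length(linked_cl2))
            group_id <- paste0(group_id, "+", ref2, ":", linked_cl2[1])
        }
      }
    }
    genes2 <- sort(unlist(genes_of_cl2[linked_cl2], use.names = FALSE))
    used_cl2 <- c(used_cl2, linked_cl2)
    seed_one(group_id, genes1, genes2 %||% character(0))
  }
  for (cid in sort(setdiff(names(genes_of_cl2), used_cl2))) {
    seed_one(paste0(ref2, ":", cid), character(0),
             sort(genes_of_cl2[[cid]]))
  }

  links <- do.call(rbind, links)
  rownames(links) <- NULL
  # similarity of each candidate to its group's reference peptide
  seqs <- pep_seq(all_peps, links$pep_id)
  for (gid in unique(links$group_id)) {
    sel <- which(links$group_id == gid)
    ref_seq <- groups[[gid]]$ref_seq
    links$similarity[sel] <- vapply(seqs[sel], function(s) {
      id <- global_identity(s, ref_seq, config)
      (id$pct_ab + id$pct_ba) / 2
    }, 0, USE.NAMES = FALSE)
  }
  structure(list(groups = groups, links = links,
                 ref_species = c(ref1, ref2), species = species),
            class = "group_set")
}

# rank ordering used everywhere a pep or candidate list is prioritized
rank_order <- function(df) {
  order(-df$confidence, -df$similarity, df$pep_id, df$group_id)
}

#' Assign every candidate peptide exclusively to a single group
#'
#' A peptide appearing in several groups' candidate pools is kept only in
#' the group where it ranks highest: confidence flag first, then global
#' identity to the group's reference peptide; full ties go to the
#' lexicographically smaller group id.
#'
#' @param gs a `group_set`.
#' @param config a [pipeline_config()].
#' @return the `group_set` with `$assigned` (exclusive candidate table) and
#'   per-group `candidates` filled in.
#' @export
assign_exclusive <- function(gs, config = pipeline_config()) {
  alive <- names(Filter(function(g) g$status != "discarded", gs$groups))
  lk <- gs$links[gs$links$group_id %in% alive, , drop = FALSE]
  lk <- lk[rank_order(lk), , drop = FALSE]
  lk <- lk[!duplicated(lk$pep_id), , drop = FALSE]
  lk <- lk[order(lk$group_id, lk$species, -lk$confidence,
                 -lk$similarity, lk$pep_id), , drop = FALSE]
  rownames(lk) <- NULL
  gs$assigned <- lk
  for (gid in names(gs$groups)) {
    if (gs$groups[[gid]]$status == "discarded") next
    gs$groups[[gid]]$candidates <-
      lk[lk$group_id == gid, , drop = FALSE]
  }
  gs
}

#' Delete sparse groups and reassign their candidates
#'
#' Groups whose candidate pool covers fewer than
#' `min_present_fraction` of the species are discarded; their candidates
#' are re-offered to the surviving groups through the same exclusive
#' ranking, iterating to a fixpoint.
#'
#' @param gs a `group_set` (after [assign_exclusive()]).
#' @param config a [pipeline_config()].
#' @return the pruned `group_set`.
#' @export
prune_sparse <- function(gs, config = pipeline_config()) {
  n_sp <- length(gs$species)
  repeat {
    gs <- assign_exclusive(gs, config)
    changed <- FALSE
    for (gid in names(gs$groups)) {
      g <- gs$groups[[gid]]
      if (g$status == "discarded") next
      cov <- length(unique(g$candidates$species)) / n_sp
      if (cov < config$min_present_fraction) {
        gs$groups[[gid]]$status <- "discarded"
        gs$groups[[gid]]$reason <- "sparse"
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  gs
}

# rebuild a group's MSA and profile from its current members
rebuild_group_profile <- function(group, pep_db, config, species_order) {
  sp <- species_order[species_order %in% names(group$members)]
  ids <- unname(unlist(group$members[sp]))
  group$msa <- build_msa(pep_seq(pep_db, ids), ids, config)
  group$profile <- build_profile(group$msa, config)
  group
}

#' Optimize a group to one best-scoring member per species
#'
#' Starts from the top-ranked candidate per species, builds the profile,
#' then iterates over species in the fixed order: an alternative
#' candidate's R against the current profile must exceed the current
#' member's R by more than `delta_improve` to be substituted; the profile
#' is rebuilt after each accepted substitution. Stops after a full pass
#' with no substitutions or after `max_passes` passes.
#'
#' @param group one group (element of `group_set$groups`) with candidates.
#' @param config a [pipeline_config()].
#' @param pep_db peptide database.
#' @param species_order fixed species order (defaults to sorted).
#' @return the optimized group, with a `substitutions` log data.frame.
#' @export
optimize_group <- function(group, config = pipeline_config(), pep_db,
                           species_order = NULL) {
  cand <- group$candidates
  species_order <- species_order %||% sort(unique(cand$species))
  subs_log <- list()
  # initial members: top-ranked candidate per species
  for (sp in species_order) {
    cs <- cand[cand$species == sp, , drop = FALSE]
    if (nrow(cs) == 0L) next
    cs <- cs[order(-cs$confidence, -cs$similarity, cs$pep_id), ,
             drop = FALSE]
    group$members[[sp]] <- cs$pep_id[1]
  }
  group <- tryCatch(
    rebuild_group_profile(group, pep_db, config, species_order),
    error = function(e) {
      group$status <- "discarded"
      group$reason <- "degenerate_profile"
      group
    })
  if (group$status == "discarded") return(group)

  for (pass in seq_len(config$max_passes)) {
    any_sub <- FALSE
    for (sp in species_order) {
      if (is.null(group$members[[sp]])) next
      cs <- cand[cand$species == sp, , drop = FALSE]
      if (nrow(cs) < 2L) next
      cur_id <- group$members[[sp]]
      cur_R <- score_profile(group$profile, pep_seq(pep_db, cur_id))$R
      alt <- cs[cs$pep_id != cur_id, , drop = FALSE]
      alt_R <- score_profile_many(group$profile,
                                  pep_seq(pep_db, alt$pep_id))
      best <- order(-alt_R, alt$pep_id)[1]
      if (alt_R[best] > cur_R + config$delta_improve) {
        group$members[[sp]] <- alt$pep_id[best]
        subs_log[[length(subs_log) + 1L]] <- data.frame(
          group_id = group$group_id, pass = pass, species = sp,
          old_pep = cur_id, new_pep = alt$pep_id[best],
          delta_R = alt_R[best] - cur_R, stringsAsFactors = FALSE)
        any_sub <- TRUE
        if (config$recompute == "per_substitution")
          group <- rebuild_group_profile(group, pep_db, config,
                                         species_order)
      }
    }
    if (config$recompute == "per_pass" && any_sub)
      group <- rebuild_group_profile(group, pep_db, config, species_order)
    if (!any_sub) break
  }
  group$member_R <- lapply(group$members, function(id)
    score_profile(group$profile, pep_seq(pep_db, id))$R)
  group$status <- "optimized"
  group$substitutions <- if (length(subs_log))
    do.call(rbind, subs_log) else NULL
  group
}

#' Offer unassigned peptides to a group under the improvement rule
#'
#' Peptides that are not members of any group, pass the raw-score hit
#' gate against the group profile, and either fill a species hole or
#' improve that species' member R by more than `delta_improve` become
#' members. The profile is rebuilt after each adoption.
#'
#' @param gs a `group_set` with optimized groups.
#' @param pep_db peptide database.
#' @param config a [pipeline_config()].
#' @param species_order fixed species order.
#' @return the updated `group_set`.
#' @export
rescue_from_unassigned <- function(gs, pep_db,
                                   config = pipeline_config(),
                                   species_order = NULL) {
  species_order <- species_order %||% gs$species
  member_ids <- unlist(lapply(gs$groups, function(g)
    unlist(g$members)), use.names = FALSE)
  pool <- pep_db[!(pep_db$pep_id %in% member_ids) &
                 pep_db$species %in% gs$species, , drop = FALSE]
  pool <- pool[order(pool$pep_id), , drop = FALSE]
  taken <- character(0)
  for (gid in sort(names(gs$groups))) {
    g <- gs$groups[[gid]]
    if (g$status != "optimized") next
    changed <- TRUE
    while (changed) {
      changed <- FALSE
      avail <- pool[!(pool$pep_id %in% taken), , drop = FALSE]
      for (sp in species_order) {
        cand <- avail[avail$species == sp, , drop = FALSE]
        if (nrow(cand) == 0L) next
        raw <- profile_raw_many(g$profile, cand$sequence)
        pass <- raw >= config$min_raw_bits
        if (!any(pass)) next
        cand <- cand[pass, , drop = FALSE]
        Rs <- raw[pass] / g$profile$max_score
        best <- order(-Rs, cand$pep_id)[1]
        adopt <- FALSE
        if (is.null(g$members[[sp]])) {
          adopt <- TRUE
        } else {
          cur_R <- score_profile(
            g$profile, pep_seq(pep_db, g$members[[sp]]))$R
          adopt <- Rs[best] > cur_R + config$delta_improve
        }
        if (adopt) {
          g$members[[sp]] <- cand$pep_id[best]
          taken <- c(taken, cand$pep_id[best])
          g <- rebuild_group_profile(g, pep_db, config, species_order)
          changed <- TRUE
        }
      }
      break  # a single sweep per group mirrors the one-shot pipeline step
    }
    gs$groups[[gid]] <- g
  }
  gs
}

#' Apply the universality filter
#'
#' A group becomes `universal` iff it has a member for every species and
#' the lowest-scoring member has R at least `r_min`; all other groups are
#' discarded with a machine-readable reason (`missing_species` or
#' `low_R`). Member R values are recomputed against the final profile.
#'
#' @param gs a `group_set`.
#' @param config a [pipeline_config()].
#' @param pep_db peptide database.
#' @param species_order fixed species order.
#' @return the finalized `group_set`.
#' @export
finalize_universal <- function(gs, config = pipeline_config(), pep_db,
                               species_order = NULL) {
  species_order <- species_order %||% gs$species
  for (gid in names(gs$groups)) {
    g <- gs$groups[[gid]]
    if (g$status == "discarded") next
    g$member_R <- lapply(g$members, function(id)
      score_profile(g$profile, pep_seq(pep_db, id))$R)
    covered <- length(g$members)
    if (covered < length(gs$species)) {
      g$status <- "discarded"; g$reason <- "missing_species"
    } else {
      g$min_R <- min(unlist(g$member_R))
      if (g$min_R < config$r_min) {
        g$status <- "discarded"; g$reason <- "low_R"
      } else {
        g$status <- "universal"
      }
    }
    gs$groups[[gid]] <- g
  }
  gs
}

universal_groups <- function(gs) {
  Filter(function(g) identical(g$status, "universal"), gs$groups)
}
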