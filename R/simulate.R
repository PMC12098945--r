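# Synthetic-data generator: truth-labelled proteomes, ortholog tables,
# genomes + GFF3 annotations, and outgroup panels with the statistical
# structure the pipeline assumes. Everything is a deterministic function of
# the seed.

#' Evolve a peptide by a given divergence
#'
#' Per-site substitution with probability `1 - exp(-distance)`; the
#' replacement residue is drawn from a fixed exchangeability-weighted
#' background distribution, so expected identity is approximately
#' `exp(-distance)` (plus a small background self-hit term) and decays to
#' background composition at large distances. Optional indels occur as
#' Poisson events with geometric lengths. Uses the current RNG state.
#'
#' @param ancestor peptide string.
#' @param distance expected substitutions per site (>= 0).
#' @param indel_rate per-site indel event rate per unit distance.
#' @param indel_mean_len mean indel length.
#' @param keep_first keep the first residue (start methionine) fixed.
#' @return the evolved peptide string.
#' @export
evolve_sequence <- function(ancestor, distance, indel_rate = 0,
                            indel_mean_len = 3, keep_first = TRUE) {
  stopifnot(distance >= 0)
  if (distance == 0) return(ancestor)
  chars <- split1(ancestor)
  n <- length(chars)
  p_sub <- 1 - exp(-distance)
  mask <- stats::runif(n) < p_sub
  if (keep_first) mask[1] <- FALSE
  if (any(mask)) {
    chars[mask] <- sample(AA20, sum(mask), replace = TRUE,
                          prob = AA_BACKGROUND)
  }
  if (indel_rate > 0) {
    n_events <- stats::rpois(1, n * indel_rate * distance)
    for (e in seq_len(n_events)) {
      len <- 1L + stats::rgeom(1, 1 / indel_mean_len)
      if (stats::runif(1) < 0.5) {  # deletion
        if (length(chars) - len >= 30L) {
          start <- sample(2:(length(chars) - len + 1L), 1L)
          chars <- chars[-(start:(start + len - 1L))]
        }
      } else {                      # insertion
        pos <- sample(seq_along(chars), 1L)
        ins <- sample(AA20, len, replace = TRUE, prob = AA_BACKGROUND)
        chars <- append(chars, ins, after = pos)
      }
    }
  }
  paste(chars, collapse = "")
}

# recursively evolve a root sequence down a balanced binary tree over the
# given tip indices; returns a list tip index -> sequence
evolve_over_tree <- function(root, tips, rate, indel_rate, indel_mean_len) {
  if (length(tips) == 1L) {
    out <- list()
    out[[as.character(tips)]] <- root
    return(out)
  }
  half <- ceiling(length(tips) / 2)
  left <- evolve_over_tree(
    evolve_sequence(root, rate, indel_rate, indel_mean_len),
    tips[seq_len(half)], rate, indel_rate, indel_mean_len)
  right <- evolve_over_tree(
    evolve_sequence(root, rate, indel_rate, indel_mean_len),
    tips[-seq_len(half)], rate, indel_rate, indel_mean_len)
  c(left, right)
}

#' Plant a near-identical duplicate of a family
#'
#' Evolves every member of a family to a target member-level identity,
#' producing the duplicate family used for supergroup tests. Uses the
#' current RNG state.
#'
#' @param members named character vector of member peptides.
#' @param identity_target target identity in (0.8, 1.0).
#' @return named character vector of duplicate member peptides.
#' @export
plant_duplication <- function(members, identity_target) {
  stopifnot(identity_target > 0.8, identity_target < 1.0)
  d <- -log(identity_target)
  vapply(members, function(s) evolve_sequence(s, d), "")
}

# random peptide of given length starting with M
random_peptide <- function(len) {
  paste(c("M", sample(AA20, len - 1L, replace = TRUE,
                      prob = AA_BACKGROUND)), collapse = "")
}

# spacer with stop codons in all six frames (palindromic stop motif)
SPACER_UNIT <- "TTAATTAATTAA"

CODONS <- local({
  b <- c("T", "C", "A", "G")
  cods <- as.vector(outer(outer(b, b, paste0), b, paste0))
  aa <- vapply(cods, function(cd) {
    as.character(Biostrings::translate(Biostrings::DNAString(cd),
                                       no.init.codon = TRUE))
  }, "")
  split(cods, aa)
})

# back-translate a peptide with random synonymous codons + TAA stop
back_translate <- function(pep) {
  chars <- split1(pep)
  cods <- vapply(chars, function(a) {
    opts <- CODONS[[a]]
    opts[sample.int(length(opts), 1L)]
  }, "")
  paste0(paste(cods, collapse = ""), "TAA")
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# which outgroup levels carry a homolog copy for each planted label
levels_with_copy <- function(label) {
  switch(label,
         non_specific = c("non_grass_commelinid", "non_commelinid_monocot",
                          "non_monocot"),
         monocot_specific = c("non_grass_commelinid",
                              "non_commelinid_monocot"),
         commelinid_specific = "non_grass_commelinid",
         grass_specific = character(0),
         stopf("unknown label %s", label))
}

#' Simulate a complete labelled input dataset
#'
#' Emits, under `out_dir`: per-species peptide FASTA files (with truncated
#' splice variants), ortholog tables for the two reference species (true
#' family links, a fraction downgraded to confidence 0 or dropped),
#' per-species single-exon genome FASTA + GFF3 (annotation dropout applied
#' to the GFF3 and peptide FASTA only, never the genome), outgroup panels
#' at three taxonomic levels honoring each family's planted specificity
#' label, a holdout species for external validation, the truth table, and
#' a ready-to-run pipeline config file. The same seed always produces
#' byte-identical files.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory.
#' @return invisible list with `dir`, `truth` (data.frame), `species`,
#'   `reference_species`, `outgroup_panel`, `holdout`, `config_path`.
#' @export
simulate_dataset <- function(config = sim_config(), out_dir) {
  set.seed(config$seed)
  n_sp <- config$n_ingroup_species
  species <- sprintf("sp%02d", seq_len(n_sp))
  half <- ceiling(n_sp / 2)
  refs <- c(species[1], species[half + 1L])
  poorly_annotated <- unique(c(species[half], species[n_sp]))
  rate <- config$substitution_rate

  n_uni <- config$n_universal_families
  n_dup <- config$n_duplicated_families
  n_dec <- config$n_decoy_families

  # planted labels: counts from weights, in weight order; the families to
  # be duplicated are forced grass_specific (no outgroup cross-talk)
  w <- config$label_weights
  counts <- diff(c(0L, round(cumsum(w * n_uni))))
  labels <- rep(names(w), counts)
  if (n_dup > 0) {
    gi <- which(labels == "grass_specific")
    stopifnot(length(gi) >= n_dup)
    dup_sources <- gi[seq_len(n_dup)]
  } else dup_sources <- integer(0)

  # --- evolve universal families down the species tree ------------------
  fam_ids <- sprintf("fam%03d", seq_len(n_uni))
  fam_root <- character(n_uni)
  members <- list()   # family -> named chr vector species -> sequence
  for (f in seq_len(n_uni)) {
    len <- max(80L, round(stats::rnorm(1, config$mean_peptide_length,
                                       config$mean_peptide_length / 5)))
    fam_root[f] <- random_peptide(len)
    tipseqs <- evolve_over_tree(fam_root[f], seq_len(n_sp), rate,
                                config$indel_rate, config$indel_mean_len)
    members[[fam_ids[f]]] <- stats::setNames(
      unlist(tipseqs[as.character(seq_len(n_sp))]), species)
  }

  # --- duplicated families ---------------------------------------------
  dup_ids <- character(0)
  dup_of <- character(0)
  for (i in seq_along(dup_sources)) {
    src <- fam_ids[dup_sources[i]]
    did <- sprintf("dup%03d", i)
    members[[did]] <- plant_duplication(members[[src]],
                                        config$duplication_identity)
    dup_ids <- c(dup_ids, did)
    dup_of <- c(dup_of, src)
  }
  labels <- c(labels, rep("grass_specific", length(dup_ids)))
  all_uni_ids <- c(fam_ids, dup_ids)

  # --- decoy families: present in at most half the species --------------
  dec_ids <- sprintf("dec%03d", seq_len(n_dec))
  dec_root <- character(n_dec)
  depth <- ceiling(log2(n_sp))
  for (d in seq_len(n_dec)) {
    len <- max(80L, round(stats::rnorm(1, config$mean_peptide_length,
                                       config$mean_peptide_length / 5)))
    dec_root[d] <- random_peptide(len)
    seed_ref <- refs[(d %% 2L) + 1L]
    others <- sample(setdiff(species, seed_ref),
                     max(1L, floor(n_sp / 2) - 1L))
    present <- c(seed_ref, others)
    members[[dec_ids[d]]] <- stats::setNames(
      vapply(present, function(s)
        evolve_sequence(dec_root[d], rate * depth,
                        config$indel_rate, config$indel_mean_len), ""),
      present)
  }
  all_fam_ids <- c(all_uni_ids, dec_ids)

  # --- splice variants --------------------------------------------------
  # variants[[fam]][[sp]] = truncated extra peptide (or NULL)
  variants <- list()
  for (fid in all_fam_ids) {
    for (sp in names(members[[fid]])) {
      if (stats::runif(1) < config$splice_variant_prob) {
        s <- members[[fid]][[sp]]
        keep <- max(30L, round(nchar(s) * stats::runif(1, 0.65, 0.85)))
        variants[[fid]][[sp]] <- substr(s, 1L, keep)
      }
    }
  }

  # --- annotation dropout (universal member entries only) ---------------
  # reference species are exempt: their annotations seed the groups, so a
  # dropped reference member would be unrecoverable even in principle
  entries <- expand.grid(family = all_uni_ids,
                         species = setdiff(species, refs),
                         stringsAsFactors = FALSE)
  entries <- entries[order(entries$family, entries$species), ]
  wts <- ifelse(entries$species %in% poorly_annotated, 5, 1)
  # the dropout budget is a fraction of ALL member entries, drawn from the
  # droppable (non-reference) ones
  n_drop <- round(config$annotation_dropout_fraction *
                    length(all_uni_ids) * n_sp)
  # isolated RNG stream: changing the dropout fraction must not disturb
  # any other simulated randomness (enables dropout vs no-dropout
  # contrasts on otherwise identical worlds)
  main_stream <- .Random.seed
  set.seed(config$seed + 7919L)
  drop_idx <- if (n_drop > 0)
    sample(nrow(entries), n_drop, prob = wts) else integer(0)
  assign(".Random.seed", main_stream, envir = globalenv())
  dropped <- entries[drop_idx, , drop = FALSE]
  is_dropped <- function(fid, sp)
    any(dropped$family == fid & dropped$species == sp)

  # --- write per-species peptide FASTA + genomes + GFF3 -----------------
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (sub in c("peps", "genomes", "gff", "orthologs", "outgroups",
                "holdout"))
    dir.create(file.path(out_dir, sub), showWarnings = FALSE)

  gene_id_of <- function(sp, fid) paste0(sp, "_", fid)
  truth <- list()
  for (sp in species) {
    rows <- list()
    gff <- c("##gff-version 3")
    chrom_parts <- character(0)
    pos <- 0L
    gidx <- 0L
    for (fid in all_fam_ids) {
      if (!(sp %in% names(members[[fid]]))) next
      gidx <- gidx + 1L
      gid <- gene_id_of(sp, fid)
      pep <- members[[fid]][[sp]]
      cds <- back_translate(pep)
      strand <- if (gidx %% 2L == 1L) "+" else "-"
      spacer <- paste(rep(SPACER_UNIT, 8L), collapse = "")
      chrom_parts <- c(chrom_parts, spacer)
      pos <- pos + nchar(spacer)
      gstart <- pos + 1L
      gseq <- if (strand == "+") cds else revcomp(cds)
      chrom_parts <- c(chrom_parts, gseq)
      pos <- pos + nchar(gseq)
      gend <- pos
      drop_this <- fid %in% all_uni_ids && is_dropped(fid, sp)
      if (!drop_this) {
        gff <- c(gff,
          sprintf("chr1\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                  gstart, gend, strand, gid),
          sprintf("chr1\tsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.1;Parent=%s",
                  gstart, gend, strand, gid, gid),
          sprintf("chr1\tsim\texon\t%d\t%d\t.\t%s\t.\tID=%s.1.e1;Parent=%s.1",
                  gstart, gend, strand, gid, gid))
        rows[[length(rows) + 1L]] <-
          data.frame(pep_id = paste0(gid, "_t1"), gene_id = gid,
                     sequence = pep, stringsAsFactors = FALSE)
        v <- if (!is.null(variants[[fid]])) variants[[fid]][[sp]] else NULL
        if (!is.null(v)) {
          rows[[length(rows) + 1L]] <-
            data.frame(pep_id = paste0(gid, "_t2"), gene_id = gid,
                       sequence = v, stringsAsFactors = FALSE)
        }
      }
      if (fid %in% all_uni_ids) {
        truth[[length(truth) + 1L]] <- data.frame(
          family_id = fid, species = sp, gene_id = gid,
          pep_id = paste0(gid, "_t1"),
          label = labels[match(fid, all_uni_ids)],
          dropped = drop_this,
          duplicate_of = if (fid %in% dup_ids)
            dup_of[match(fid, dup_ids)] else NA_character_,
          start = gstart, end = gend, strand = strand,
          stringsAsFactors = FALSE)
      }
    }
    tail_spacer <- paste(rep(SPACER_UNIT, 8L), collapse = "")
    chrom <- paste(c(chrom_parts, tail_spacer), collapse = "")
    pepdf <- do.call(rbind, rows)
    ps <- new_pep_set(pep_id = pepdf$pep_id, gene_id = pepdf$gene_id,
                      species = sp, sequence = pepdf$sequence)
    write_peptides(ps, file.path(out_dir, "peps", paste0(sp, ".fasta")))
    dna <- Biostrings::DNAStringSet(chrom)
    names(dna) <- "chr1"
    Biostrings::writeXStringSet(
      dna, file.path(out_dir, "genomes", paste0(sp, ".fasta")),
      width = 80L)
    writeLines(gff, file.path(out_dir, "gff", paste0(sp, ".gff3")))
  }
  truth <- do.call(rbind, truth)

  # --- ortholog tables for the two reference species --------------------
  annotated <- function(fid, sp) {
    sp %in% names(members[[fid]]) &&
      !(fid %in% all_uni_ids && is_dropped(fid, sp))
  }
  for (ref in refs) {
    rows <- list()
    for (fid in all_fam_ids) {
      for (sp in setdiff(species, ref)) {
        # noise draws happen for every potential row so that annotation
        # dropout does not shift the RNG stream
        u_drop <- stats::runif(1)
        u_conf <- stats::runif(1)
        if (!annotated(fid, ref) || !annotated(fid, sp)) next
        if (u_drop < config$row_dropout) next
        conf <- if (u_conf < config$confidence_downgrade) 0L else 1L
        rows[[length(rows) + 1L]] <- data.frame(
          ref_gene = gene_id_of(ref, fid), target_species = sp,
          target_gene = gene_id_of(sp, fid), confidence = conf,
          stringsAsFactors = FALSE)
      }
    }
    tab <- do.call(rbind, rows)
    utils::write.table(tab, file.path(out_dir, "orthologs",
                                      paste0(ref, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- outgroup panels --------------------------------------------------
  og_levels <- names(config$outgroup_depths)
  panel <- list()
  shallow <- config$outgroup_depths[[1]]
  for (lv in og_levels) {
    for (i in seq_len(config$outgroup_counts[[lv]])) {
      og_sp <- sprintf("og_%s_%d", lv, i)
      rows <- list()
      for (f in seq_along(all_uni_ids)) {
        fid <- all_uni_ids[f]
        if (!(lv %in% levels_with_copy(labels[f]))) next
        root <- if (fid %in% dup_ids)
          members[[fid]][[refs[1]]] else fam_root[match(fid, fam_ids)]
        seqv <- evolve_sequence(root, shallow, config$indel_rate,
                                config$indel_mean_len)
        gid <- paste0(og_sp, "_", fid)
        rows[[length(rows) + 1L]] <- data.frame(
          pep_id = paste0(gid, "_t1"), gene_id = gid, sequence = seqv,
          stringsAsFactors = FALSE)
      }
      # distant homolog background: decoy roots at the level's depth
      for (d in seq_len(n_dec)) {
        seqv <- evolve_sequence(dec_root[d], config$outgroup_depths[[lv]],
                                config$indel_rate, config$indel_mean_len)
        gid <- paste0(og_sp, "_", dec_ids[d])
        rows[[length(rows) + 1L]] <- data.frame(
          pep_id = paste0(gid, "_t1"), gene_id = gid, sequence = seqv,
          stringsAsFactors = FALSE)
      }
      for (b in seq_len(config$n_background_outgroup)) {
        gid <- sprintf("%s_bg%03d", og_sp, b)
        rows[[length(rows) + 1L]] <- data.frame(
          pep_id = paste0(gid, "_t1"), gene_id = gid,
          sequence = random_peptide(200L), stringsAsFactors = FALSE)
      }
      pepdf <- do.call(rbind, rows)
      ps <- new_pep_set(pep_id = pepdf$pep_id, gene_id = pepdf$gene_id,
                        species = og_sp, sequence = pepdf$sequence)
      write_peptides(ps, file.path(out_dir, "outgroups",
                                   paste0(og_sp, ".fasta")))
      panel[[length(panel) + 1L]] <- data.frame(
        species = og_sp, level = lv, stringsAsFactors = FALSE)
    }
  }
  panel <- do.call(rbind, panel)
  utils::write.table(panel, file.path(out_dir, "outgroups", "panel.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- holdout validation species --------------------------------------
  holdout <- character(0)
  for (h in seq_len(config$n_holdout)) {
    ho <- sprintf("holdout%d", h)
    holdout <- c(holdout, ho)
    rows <- list()
    chrom_parts <- character(0)
    gidx <- 0L
    for (fid in all_uni_ids) {
      root <- if (fid %in% dup_ids)
        members[[fid]][[refs[1]]] else fam_root[match(fid, fam_ids)]
      pep <- evolve_sequence(root, config$holdout_divergence,
                             config$indel_rate, config$indel_mean_len)
      gidx <- gidx + 1L
      gid <- gene_id_of(ho, fid)
      rows[[length(rows) + 1L]] <- data.frame(
        pep_id = paste0(gid, "_t1"), gene_id = gid, sequence = pep,
        stringsAsFactors = FALSE)
      cds <- back_translate(pep)
      strand <- if (gidx %% 2L == 1L) "+" else "-"
      gseq <- if (strand == "+") cds else revcomp(cds)
      chrom_parts <- c(chrom_parts,
                       paste(rep(SPACER_UNIT, 8L), collapse = ""), gseq)
    }
    chrom_parts <- c(chrom_parts, paste(rep(SPACER_UNIT, 8L),
                                        collapse = ""))
    pepdf <- do.call(rbind, rows)
    ps <- new_pep_set(pep_id = pepdf$pep_id, gene_id = pepdf$gene_id,
                      species = ho, sequence = pepdf$sequence)
    write_peptides(ps, file.path(out_dir, "holdout",
                                 paste0(ho, ".pep.fasta")))
    dna <- Biostrings::DNAStringSet(paste(chrom_parts, collapse = ""))
    names(dna) <- "chr1"
    Biostrings::writeXStringSet(
      dna, file.path(out_dir, "holdout", paste0(ho, ".genome.fasta")),
      width = 80L)
  }

  # --- truth table and pipeline config ---------------------------------
  utils::write.table(truth, file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg_path <- file.path(out_dir, "pipeline.cfg")
  lines <- c(
    paste0("species = ", paste(species, collapse = ",")),
    paste0("reference_species = ", paste(refs, collapse = ",")),
    paste0("out_dir = ", file.path(out_dir, "results")),
    vapply(species, function(sp)
      sprintf("peptides.%s = %s", sp,
              file.path(out_dir, "peps", paste0(sp, ".fasta"))), ""),
    vapply(species, function(sp)
      sprintf("genome.%s = %s", sp,
              file.path(out_dir, "genomes", paste0(sp, ".fasta"))), ""),
    vapply(species, function(sp)
      sprintf("gff.%s = %s", sp,
              file.path(out_dir, "gff", paste0(sp, ".gff3"))), ""),
    vapply(refs, function(ref)
      sprintf("ortholog_table.%s = %s", ref,
              file.path(out_dir, "orthologs", paste0(ref, ".tsv"))), ""),
    vapply(seq_len(nrow(panel)), function(i)
      sprintf("outgroup.%s = %s:%s", panel$species[i], panel$level[i],
              file.path(out_dir, "outgroups",
                        paste0(panel$species[i], ".fasta"))), ""))
  writeLines(lines, cfg_path)

  invisible(list(dir = out_dir, truth = truth, species = species,
                 reference_species = refs, outgroup_panel = panel,
                 holdout = holdout, labels = stats::setNames(
                   labels, all_uni_ids),
                 config_path = cfg_path, config = config))
}
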