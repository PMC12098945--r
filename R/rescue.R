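# Gene-model rescue from genomic sequence: a pluggable gene-finder adapter
# with a built-in six-frame single-exon ORF stub, novelty checking against
# annotated exon coordinates, and adoption under the improvement rule and
# the rescued-member caps.

#' Index all ORFs of a genome (built-in adapter backend)
#'
#' Six-frame scan for open reading frames (ATG...stop) of at least
#' `min_aa` residues, single-exon only. Coordinates are 1-based inclusive
#' on the forward strand and include the stop codon.
#'
#' @param genome a named `DNAStringSet` (or path to a genome FASTA).
#' @param min_aa minimum peptide length.
#' @return data.frame with `chrom`, `strand`, `start`, `end`, `peptide`.
#' @export
orf_index <- function(genome, min_aa = 30L) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  out <- list()
  for (ci in seq_along(genome)) {
    chrom <- names(genome)[ci] %||% as.character(ci)
    s <- as.character(genome[[ci]])
    L <- nchar(s)
    for (strand in c("+", "-")) {
      seqf <- if (strand == "+") s else revcomp(s)
      for (f in 0:2) {
        sub <- substr(seqf, f + 1L, L)
        sub <- substr(sub, 1L, nchar(sub) - nchar(sub) %% 3L)
        if (nchar(sub) < 3L) next
        prot <- as.character(Biostrings::translate(
          Biostrings::DNAString(sub), no.init.codon = TRUE,
          if.fuzzy.codon = "X"))
        pat <- sprintf("M[^*]{%d,}\\*", min_aa - 1L)
        m <- gregexpr(pat, prot)[[1]]
        if (m[1] == -1L) next
        for (k in seq_along(m)) {
          aa_start <- m[k]
          aa_len <- attr(m, "match.length")[k]   # includes the stop
          pep <- substr(prot, aa_start, aa_start + aa_len - 2L)
          nt_start_f <- f + 3L * (aa_start - 1L) + 1L
          nt_end_f <- f + 3L * (aa_start - 1L + aa_len)
          if (strand == "+") {
            st <- nt_start_f; en <- nt_end_f
          } else {
            st <- L - nt_end_f + 1L; en <- L - nt_start_f + 1L
          }
          out[[length(out) + 1L]] <- data.frame(
            chrom = chrom, strand = strand, start = st, end = en,
            peptide = pep, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(), strand = character(),
                      start = integer(), end = integer(),
                      peptide = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start, res$strand), , drop = FALSE]
}

#' Find candidate gene models for a group in a genome
#'
#' Runs the configured gene-finder adapter with the group consensus as
#' query. The built-in stub scans six-frame single-exon ORFs, keeps those
#' passing the raw-score hit gate against the group profile, and ranks by
#' adapter score (the raw bit score) descending. An external adapter can
#' be supplied as `function(genome, query) -> model data.frame`; adapter
#' failures are reported and yield an empty candidate list.
#'
#' @param genome `DNAStringSet`, genome FASTA path, or a precomputed
#'   [orf_index()] data.frame (fastest when rescuing many groups).
#' @param profile the group's `profile_model` (query = its consensus).
#' @param species species label for emitted models.
#' @param config a [pipeline_config()].
#' @param adapter optional external adapter function.
#' @return list of `rescued_model` lists, sorted by adapter score
#'   descending.
#' @export
find_candidate_models <- function(genome, profile, species,
                                  config = pipeline_config(),
                                  adapter = NULL) {
  orfs <- tryCatch({
    if (is.data.frame(genome)) genome
    else if (!is.null(adapter)) adapter(genome, profile$consensus)
    else orf_index(genome)
  }, error = function(e) {
    warning("rescue adapter failed: ", conditionMessage(e))
    NULL
  })
  if (is.null(orfs) || nrow(orfs) == 0L) return(list())
  raw <- profile_raw_many(profile, orfs$peptide)
  models <- list()
  for (i in which(raw >= config$min_raw_bits)) {
    models[[length(models) + 1L]] <- structure(list(
      species = species, chrom = orfs$chrom[i], strand = orfs$strand[i],
      exons = data.frame(start = orfs$start[i], end = orfs$end[i]),
      peptide = orfs$peptide[i], adapter_score = raw[i],
      R = raw[i] / profile$max_score),
      class = "rescued_model")
  }
  if (length(models) == 0L) return(models)
  models[order(-vapply(models, `[[`, 0, "adapter_score"),
               vapply(models, function(m) m$exons$start[1], 0L))]
}

#' Is a rescued model novel relative to the annotation?
#'
#' `FALSE` iff any exon of the model overlaps any annotated exon on the
#' same chromosome and strand by at least 1 bp.
#'
#' @param model a `rescued_model`.
#' @param annotation_index an `annotation_index` for the same species.
#' @return logical.
#' @export
is_novel <- function(model, annotation_index) {
  ann <- annotation_index[annotation_index$chrom %in% model$chrom &
                          annotation_index$strand %in% model$strand, ,
                          drop = FALSE]
  if (nrow(ann) == 0L) return(TRUE)
  hits <- IRanges::findOverlaps(
    IRanges::IRanges(model$exons$start, model$exons$end),
    IRanges::IRanges(ann$start, ann$end))
  length(hits) == 0L
}

#' Adopt rescued models into a group under the caps
#'
#' Candidate models (already novelty-checked) are offered per species:
#' species with no member first, then members below `r_min` in ascending
#' R; within a species the best model by R wins. A model is adopted iff it
#' fills a hole or improves that member's R by more than `delta_improve`,
#' subject to at most `max_rescued` rescued members per group and at least
#' `ceil(min_present_fraction * n_species)` annotated members. The profile
#' is rebuilt after each adoption.
#'
#' @param group an optimized group.
#' @param models_by_species named list: species -> list of
#'   `rescued_model`s.
#' @param config a [pipeline_config()].
#' @param pep_db peptide database; adopted peptides are appended.
#' @param species_order fixed species order.
#' @param n_species total number of ingroup species.
#' @return list(group, pep_db, adopted): the updated group, the extended
#'   peptide database, and a data.frame of adopted models.
#' @export
adopt_rescued <- function(group, models_by_species,
                          config = pipeline_config(), pep_db,
                          species_order = NULL, n_species = NULL) {
  species_order <- species_order %||% sort(names(models_by_species))
  n_species <- n_species %||% length(species_order)
  min_annotated <- ceiling(config$min_present_fraction * n_species)
  adopted <- list()

  n_annotated <- function(g) {
    ids <- unlist(g$members)
    sum(pep_db$source[match(ids, pep_db$pep_id)] == "annotated")
  }
  member_R_of <- function(g, sp)
    score_profile(g$profile, pep_seq(pep_db, g$members[[sp]]))$R

  holes <- species_order[vapply(species_order, function(sp)
    is.null(group$members[[sp]]), TRUE)]
  lows <- setdiff(names(models_by_species), holes)
  if (length(lows)) {
    lowR <- vapply(lows, function(sp) member_R_of(group, sp), 0)
    lows <- lows[order(lowR, lows)]
  }
  for (sp in c(holes[holes %in% names(models_by_species)], lows)) {
    if (group$n_rescued >= config$max_rescued) break
    models <- models_by_species[[sp]]
    if (length(models) == 0L) next
    Rs <- vapply(models, function(m)
      score_profile(group$profile, m$peptide)$R, 0)
    best <- order(-Rs)[1]
    fills_hole <- is.null(group$members[[sp]])
    ok <- if (fills_hole) TRUE else {
      Rs[best] > member_R_of(group, sp) + config$delta_improve
    }
    if (!ok) next
    # replacing an annotated member must not break the annotated floor
    if (!fills_hole && n_annotated(group) - 1L < min_annotated) next
    m <- models[[best]]
    pid <- sprintf("rescued|%s|%s", group$group_id, sp)
    pep_db <- rbind(pep_db, data.frame(
      pep_id = pid, gene_id = pid, species = sp, sequence = m$peptide,
      source = "rescued", stringsAsFactors = FALSE))
    rownames(pep_db) <- pep_db$pep_id
    group$members[[sp]] <- pid
    group$n_rescued <- group$n_rescued + 1L
    adopted[[length(adopted) + 1L]] <- data.frame(
      group_id = group$group_id, species = sp, pep_id = pid,
      chrom = m$chrom, strand = m$strand, start = m$exons$start[1],
      end = m$exons$end[1], R = Rs[best], stringsAsFactors = FALSE)
    group <- rebuild_group_profile(group, pep_db, config, species_order)
  }
  list(group = group,
       pep_db = pep_db,
       adopted = if (length(adopted)) do.call(rbind, adopted) else NULL)
}

#' Rescue missing or low-scoring members for all groups from genomes
#'
#' For every optimized group and every species whose member is missing or
#' scores below `r_min`, searches that species' genome with the group
#' consensus, filters to novel models, and adopts them under the caps.
#'
#' @param gs a `group_set` after [rescue_from_unassigned()].
#' @param genomes named list: species -> `DNAStringSet`, FASTA path, or
#'   [orf_index()] data.frame.
#' @param annotations named list: species -> `annotation_index`.
#' @param pep_db peptide database.
#' @param config a [pipeline_config()].
#' @param species_order fixed species order.
#' @param adapter optional external adapter.
#' @return list(gs, pep_db, adopted) with the rescue log.
#' @export
rescue_groups <- function(gs, genomes, annotations, pep_db,
                          config = pipeline_config(),
                          species_order = NULL, adapter = NULL) {
  species_order <- species_order %||% gs$species
  # precompute ORF indices once per species
  idx <- lapply(genomes, function(g)
    if (is.data.frame(g)) g else orf_index(g))
  logs <- list()
  for (gid in sort(names(gs$groups))) {
    g <- gs$groups[[gid]]
    if (g$status != "optimized") next
    targets <- character(0)
    for (sp in species_order) {
      if (is.null(g$members[[sp]])) targets <- c(targets, sp)
      else {
        R <- score_profile(g$profile,
                           pep_seq(pep_db, g$members[[sp]]))$R
        if (R < config$r_min) targets <- c(targets, sp)
      }
    }
    targets <- targets[targets %in% names(idx)]
    if (length(targets) == 0L) next
    models_by_species <- list()
    for (sp in targets) {
      models <- find_candidate_models(idx[[sp]], g$profile, sp, config,
                                      adapter)
      models <- Filter(function(m) is_novel(m, annotations[[sp]]), models)
      if (length(models)) models_by_species[[sp]] <- models
    }
    if (length(models_by_species) == 0L) next
    res <- adopt_rescued(g, models_by_species, config, pep_db,
                         species_order, length(gs$species))
    gs$groups[[gid]] <- res$group
    pep_db <- res$pep_db
    if (!is.null(res$adopted))
      logs[[length(logs) + 1L]] <- res$adopted
  }
  list(gs = gs, pep_db = pep_db,
       adopted = if (length(logs)) do.call(rbind, logs) else NULL)
}

#' Write rescued models as GFF3 and FASTA
#' @param adopted data.frame from [rescue_groups()].
#' @param gff_path,fasta_path output paths.
#' @export
write_rescued <- function(adopted, gff_path, fasta_path, pep_db) {
  lines <- "##gff-version 3"
  if (!is.null(adopted) && nrow(adopted) > 0L) {
    for (i in seq_len(nrow(adopted))) {
      gid <- gsub("[|]", "_", adopted$pep_id[i])
      lines <- c(lines,
        sprintf("%s\trescue\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                adopted$chrom[i], adopted$start[i], adopted$end[i],
                adopted$strand[i], gid),
        sprintf("%s\trescue\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.1;Parent=%s",
                adopted$chrom[i], adopted$start[i], adopted$end[i],
                adopted$strand[i], gid, gid),
        sprintf("%s\trescue\texon\t%d\t%d\t.\t%s\t.\tID=%s.1.e1;Parent=%s.1",
                adopted$chrom[i], adopted$start[i], adopted$end[i],
                adopted$strand[i], gid, gid))
    }
  }
  writeLines(lines, gff_path)
  seqs <- pep_db[match(adopted$pep_id, pep_db$pep_id), , drop = FALSE]
  if (!is.null(adopted) && nrow(adopted) > 0L) {
    aa <- Biostrings::AAStringSet(seqs$sequence)
    names(aa) <- seqs$pep_id
    Biostrings::writeXStringSet(aa, fasta_path, width = 80L)
  } else {
    writeLines(character(0), fasta_path)
  }
  invisible(NULL)
}
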