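# Reading and writing of all standard formats the pipeline touches:
# peptide FASTA (with the dedup rule), ortholog TSV, GFF3 annotation
# indices, and the final group tables.

#' Read a species peptide set from FASTA
#'
#' Reads one species' peptide FASTA. Identical sequences are collapsed to
#' the first-seen record; non-identical peptides from splice variants of the
#' same gene are all retained, in order of first appearance. A terminal
#' `*` (stop) is stripped; an internal `*` or any character outside the
#' 20-letter amino-acid alphabet plus `X` is an error reporting the
#' position. The gene id is taken from a `gene:<id>` token in the FASTA
#' description, falling back to the record id.
#'
#' @param fasta_path path to a peptide FASTA file.
#' @param species species label for every record (not parsed from headers).
#' @return a `species_pep_set`: a data.frame with columns `pep_id`,
#'   `gene_id`, `species`, `sequence`, `source`.
#' @export
read_peptides <- function(fasta_path, species) {
  if (!file.exists(fasta_path))
    stopf("peptide FASTA not readable: %s", fasta_path)
  aa <- Biostrings::readAAStringSet(fasta_path)
  if (length(aa) == 0L) return(new_pep_set(species = species))
  headers <- names(aa)
  pep_id <- vapply(strsplit(headers, "\\s+"), `[`, "", 1L)
  gene_id <- vapply(headers, function(h) {
    m <- regmatches(h, regexpr("gene:[^ \t]+", h))
    if (length(m) == 1L) sub("^gene:", "", m) else NA_character_
  }, "", USE.NAMES = FALSE)
  gene_id <- ifelse(is.na(gene_id), pep_id, gene_id)
  seqs <- as.character(aa)
  seqs <- vapply(seq_along(seqs),
                 function(i) clean_peptide(seqs[i], pep_id[i]), "")
  if (anyDuplicated(pep_id))
    stopf("duplicate peptide id '%s' in %s",
          pep_id[which(duplicated(pep_id))[1]], fasta_path)
  keep <- !duplicated(seqs)   # dedup identical sequences, first kept
  new_pep_set(pep_id = pep_id[keep], gene_id = gene_id[keep],
              species = species, sequence = unname(seqs[keep]))
}

#' Construct a `species_pep_set` from vectors
#' @param pep_id,gene_id,species,sequence,source record fields.
#' @return a `species_pep_set` data.frame.
#' @export
new_pep_set <- function(pep_id = character(), gene_id = character(),
                        species = character(0), sequence = character(),
                        source = "annotated") {
  sp <- if (length(pep_id) == 0L) character() else
    rep_len(species, length(pep_id))
  df <- data.frame(pep_id = pep_id, gene_id = gene_id, species = sp,
                   sequence = sequence,
                   source = rep_len(source, length(pep_id)),
                   stringsAsFactors = FALSE)
  attr(df, "species_label") <- if (length(species)) species[1] else NA
  class(df) <- c("species_pep_set", "data.frame")
  df
}

#' Write a species peptide set to FASTA
#'
#' Headers carry the peptide id and a `gene:<id>` token, so
#' `read_peptides()` on the output reproduces the set.
#'
#' @param peps a `species_pep_set` (or compatible data.frame).
#' @param path output FASTA path.
#' @export
write_peptides <- function(peps, path) {
  aa <- Biostrings::AAStringSet(peps$sequence)
  names(aa) <- paste0(peps$pep_id, " gene:", peps$gene_id)
  Biostrings::writeXStringSet(aa, path, width = 80L)
  invisible(path)
}

#' Read an ortholog table
#'
#' A TSV with named columns `ref_gene`, `target_species`, `target_gene`,
#' `confidence` (0 or 1). Rows with any other confidence value are an
#' error naming the row.
#'
#' @param tsv_path path to the TSV.
#' @param reference_species the reference species the `ref_gene` column
#'   belongs to.
#' @return a data.frame of class `ortholog_table` with attribute
#'   `reference_species`.
#' @export
read_ortholog_table <- function(tsv_path, reference_species = NA_character_) {
  if (!file.exists(tsv_path))
    stopf("ortholog table not readable: %s", tsv_path)
  df <- utils::read.delim(tsv_path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("ref_gene", "target_species", "target_gene", "confidence")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L)
    stopf("ortholog table %s missing column(s): %s", tsv_path,
          paste(missing_cols, collapse = ", "))
  df <- df[, need]
  conf <- suppressWarnings(as.integer(df$confidence))
  bad <- which(is.na(conf) | !(conf %in% c(0L, 1L)))
  if (length(bad) > 0L)
    stopf("ortholog table %s: confidence outside {0,1} in row %d ('%s')",
          tsv_path, bad[1], df$confidence[bad[1]])
  df$confidence <- conf
  attr(df, "reference_species") <- reference_species
  class(df) <- c("ortholog_table", "data.frame")
  df
}

#' Write an ortholog table
#' @param tab an `ortholog_table` data.frame.
#' @param path output TSV path.
#' @export
write_ortholog_table <- function(tab, path) {
  utils::write.table(as.data.frame(tab)[, c("ref_gene", "target_species",
                                            "target_gene", "confidence")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene annotation index from GFF3
#'
#' Collects exon intervals (1-based, inclusive) grouped by gene, retaining
#' chromosome and strand. Exons must resolve to a parent gene through their
#' mRNA `Parent` attribute (or directly); intervals within a gene must be
#' non-overlapping and are returned sorted by start.
#'
#' @param gff3_path path to a GFF3 file.
#' @param species species label.
#' @return an `annotation_index`: a data.frame with columns `gene_id`,
#'   `chrom`, `strand`, `start`, `end` (one row per exon).
#' @export
read_annotations <- function(gff3_path, species) {
  if (!file.exists(gff3_path))
    stopf("GFF3 not readable: %s", gff3_path)
  g <- as.data.frame(rtracklayer::readGFF(
    gff3_path, columns = c("seqid", "type", "start", "end", "strand"),
    tags = c("ID", "Parent")))
  g$Parent <- vapply(g$Parent,
                     function(p) if (length(p)) as.character(p)[1]
                                 else NA_character_, "")
  if (any(is.na(g$start) | is.na(g$end)) || any(g$end < g$start))
    stopf("malformed coordinates in %s", gff3_path)
  mrna <- g[g$type == "mRNA", ]
  gene_of_mrna <- stats::setNames(mrna$Parent, mrna$ID)
  ex <- g[g$type == "exon", ]
  if (nrow(ex) == 0L) {
    idx <- data.frame(gene_id = character(), chrom = character(),
                      strand = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  } else {
    parent_gene <- ifelse(ex$Parent %in% names(gene_of_mrna),
                          unname(gene_of_mrna[ex$Parent]), ex$Parent)
    known_genes <- g$ID[g$type == "gene"]
    orphan <- is.na(parent_gene) |
      (!(parent_gene %in% known_genes) & !(ex$Parent %in% known_genes))
    if (any(orphan))
      stopf("exon without parent gene in %s (exon at %s:%d-%d)",
            gff3_path, ex$seqid[which(orphan)[1]],
            ex$start[which(orphan)[1]], ex$end[which(orphan)[1]])
    idx <- data.frame(gene_id = parent_gene,
                      chrom = as.character(ex$seqid),
                      strand = as.character(ex$strand),
                      start = as.integer(ex$start),
                      end = as.integer(ex$end),
                      stringsAsFactors = FALSE)
    idx <- idx[order(idx$gene_id, idx$start), ]
    rownames(idx) <- NULL
    # overlap check within genes (sorted by start)
    for (gid in unique(idx$gene_id)) {
      iv <- idx[idx$gene_id == gid, ]
      if (nrow(iv) > 1L && any(iv$start[-1] <= iv$end[-nrow(iv)]))
        stopf("overlapping exon intervals for gene %s in %s", gid, gff3_path)
    }
  }
  attr(idx, "species_label") <- species
  class(idx) <- c("annotation_index", "data.frame")
  idx
}

#' Write the final group tables
#'
#' Materializes the pipeline output: a membership TSV (`group_id`,
#' `species`, `pep_id`, `source`, `R`), a specificity TSV, one MSA FASTA and
#' one plain-text profile file per group. Row order is deterministic:
#' groups by id, then the fixed species order.
#'
#' @param gs a `group_set` with finalized groups.
#' @param specificity_results data.frame from [specificity_table()], or
#'   `NULL`.
#' @param out_dir output directory (created if needed).
#' @param pep_db peptide database (see [build_pep_db()]).
#' @param config a [pipeline_config()].
#' @return invisible character vector of files written.
#' @export
write_group_tables <- function(gs, specificity_results, out_dir, pep_db,
                               config = pipeline_config()) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stopf("cannot create output directory %s", out_dir)
  msa_dir <- file.path(out_dir, "msa")
  prof_dir <- file.path(out_dir, "profiles")
  dir.create(msa_dir, showWarnings = FALSE)
  dir.create(prof_dir, showWarnings = FALSE)

  groups <- if (length(gs$groups))
    gs$groups[order(names(gs$groups))] else list()
  universal <- Filter(function(g) identical(g$status, "universal"), groups)
  sp_order <- config$species_order %||% sort(unique(pep_db$species))

  mem <- do.call(rbind, c(list(
    data.frame(group_id = character(), species = character(),
               pep_id = character(), source = character(), R = numeric())),
    lapply(universal, function(g) {
      sp <- sp_order[sp_order %in% names(g$members)]
      data.frame(group_id = g$group_id, species = sp,
                 pep_id = unname(unlist(g$members[sp])),
                 source = pep_db$source[match(unlist(g$members[sp]),
                                              pep_db$pep_id)],
                 R = unname(unlist(g$member_R[sp])),
                 stringsAsFactors = FALSE)
    })))
  files <- file.path(out_dir, "membership.tsv")
  utils::write.table(mem, files[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  if (!is.null(specificity_results)) {
    spec <- specificity_results[order(specificity_results$group_id), ,
                                drop = FALSE]
    f <- file.path(out_dir, "specificity.tsv")
    utils::write.table(spec, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }

  for (g in universal) {
    if (!is.null(g$msa)) {
      f <- file.path(msa_dir, paste0(g$group_id, ".fasta"))
      aa <- Biostrings::AAStringSet(g$msa$seqs)
      names(aa) <- g$msa$pep_ids
      Biostrings::writeXStringSet(aa, f, width = 80L)
      files <- c(files, f)
    }
    if (!is.null(g$profile)) {
      f <- file.path(prof_dir, paste0(g$group_id, ".tsv"))
      write_profile(g$profile, f)
      files <- c(files, f)
    }
  }
  invisible(files)
}
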