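#' Pipeline configuration
#'
#' Assembles the full set of thresholds and tuning parameters used by the
#' group-building pipeline. Defaults implement the published calibration:
#' the universality cutoff `r_min = 0.65` on the relative score R, the
#' substitution-acceptance margin `delta_improve = 0.01`, bidirectional
#' clustering identity of 90%, a minimum species coverage of 3/4 (the
#' "at most four of sixteen missing" rule generalized to any species count),
#' at most four genome-rescued members per group, and the specificity
#' cutoff S > 0.25.
#'
#' @param r_min minimum relative score R of the lowest-scoring member for a
#'   group to count as universal.
#' @param delta_improve margin by which a candidate's R must exceed the
#'   current member's R for a substitution to be accepted (strict).
#' @param cluster_identity_pct bidirectional percent-identity threshold
#'   (strict) for collapsing reference-species peptides into clusters.
#' @param min_present_fraction minimum fraction of species that must have a
#'   candidate/member for a group to survive pruning; also sets the floor on
#'   annotated (non-rescued) members.
#' @param max_rescued maximum number of genome-rescued members per group.
#' @param specificity_cutoff S value that must be strictly exceeded to call
#'   a group specific at a taxonomic depth.
#' @param min_raw_bits raw bit-score gate applied before any R comparison;
#'   the internal analogue of an E-value threshold.
#' @param penalties named numeric vector of profile alignment penalties in
#'   bits: `delete` per skipped match state, `insert_open`, `insert_extend`.
#' @param max_passes cap on optimization passes over the species list.
#' @param species_order fixed species evaluation order; `NULL` means sorted.
#' @param occupancy_threshold minimum non-gap column occupancy (inclusive)
#'   for an alignment column to become a profile match state.
#' @param pseudocount total pseudocount mass added to column emission counts.
#' @param gap_open,gap_ext affine gap penalties (positive costs) for the
#'   progressive aligner and pairwise identity alignments.
#' @param min_seed_identity minimum mean percent identity for a cross
#'   reference best-hit to seed a composite group.
#' @param supergroup_mode `"components"` (default) or `"clique"`; how mutual
#'   above-threshold group pairs are agglomerated into supergroups.
#' @param recompute `"per_substitution"` (default) rebuilds the profile after
#'   every accepted substitution; `"per_pass"` rebuilds once per pass.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(r_min = 0.65,
                            delta_improve = 0.01,
                            cluster_identity_pct = 90,
                            min_present_fraction = 0.75,
                            max_rescued = 4,
                            specificity_cutoff = 0.25,
                            min_raw_bits = 10,
                            penalties = c(delete = 2, insert_open = 3,
                                          insert_extend = 1),
                            max_passes = 5,
                            species_order = NULL,
                            occupancy_threshold = 0.5,
                            pseudocount = 1,
                            gap_open = 11,
                            gap_ext = 1,
                            min_seed_identity = 30,
                            supergroup_mode = c("components", "clique"),
                            recompute = c("per_substitution", "per_pass")) {
  stopifnot(r_min > 0, r_min <= 1,
            delta_improve >= 0,
            cluster_identity_pct > 0, cluster_identity_pct <= 100,
            min_present_fraction > 0, min_present_fraction <= 1,
            max_rescued >= 0,
            min_raw_bits >= 0,
            all(c("delete", "insert_open", "insert_extend")
                %in% names(penalties)),
            max_passes >= 1)
  cfg <- list(
    r_min = r_min, delta_improve = delta_improve,
    cluster_identity_pct = cluster_identity_pct,
    min_present_fraction = min_present_fraction,
    max_rescued = max_rescued,
    specificity_cutoff = specificity_cutoff,
    min_raw_bits = min_raw_bits,
    penalties = penalties,
    max_passes = max_passes,
    species_order = species_order,
    occupancy_threshold = occupancy_threshold,
    pseudocount = pseudocount,
    gap_open = gap_open, gap_ext = gap_ext,
    min_seed_identity = min_seed_identity,
    supergroup_mode = match.arg(supergroup_mode),
    recompute = match.arg(recompute))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Synthetic-data generator configuration
#'
#' Describes the simulated world: a balanced ingroup clade with planted
#' universal families, sparse decoy families, near-identical duplicated
#' families, splice variants, annotation dropout concentrated in two
#' "poorly annotated" species, and outgroup panels at three taxonomic
#' depths with presence/absence following each family's planted
#' specificity label.
#'
#' @param seed integer seed; fully determines all output.
#' @param n_ingroup_species number of ingroup species.
#' @param n_universal_families families planted in every ingroup species.
#' @param n_decoy_families families planted in at most half the species.
#' @param n_duplicated_families how many universal families receive a
#'   near-identical duplicate (extra families, for supergroup tests).
#' @param substitution_rate expected substitutions per site per tree branch.
#' @param indel_rate per-site indel event rate per unit distance.
#' @param indel_mean_len mean indel length (geometric).
#' @param splice_variant_prob probability a gene gets a truncated splice
#'   variant peptide in addition to its primary peptide.
#' @param annotation_dropout_fraction fraction of planted member genes whose
#'   annotation (GFF3 entry and peptide) is deleted while the genomic copy
#'   is kept intact.
#' @param outgroup_depths named increasing divergence depths (substitutions
#'   per site) for the three outgroup levels.
#' @param outgroup_counts species per outgroup level.
#' @param mean_peptide_length mean planted peptide length (residues).
#' @param duplication_identity member-level target identity for duplicated
#'   families planted by `simulate_dataset` (kept below the 90% clustering
#'   threshold so the two copies seed distinct groups).
#' @param label_weights relative frequencies of planted specificity labels
#'   for universal families.
#' @param confidence_downgrade fraction of ortholog rows downgraded to
#'   confidence 0.
#' @param row_dropout fraction of ortholog rows deleted.
#' @param n_background_outgroup unrelated background peptides per outgroup
#'   species.
#' @param holdout_divergence divergence of the holdout validation species.
#' @param n_holdout number of holdout species (excluded from the pipeline
#'   inputs; used for external validation tests).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_ingroup_species = 8,
                       n_universal_families = 30,
                       n_decoy_families = 10,
                       n_duplicated_families = 2,
                       substitution_rate = 0.05,
                       indel_rate = 0.002,
                       indel_mean_len = 3,
                       splice_variant_prob = 0.3,
                       annotation_dropout_fraction = 0.1,
                       outgroup_depths = c(non_grass_commelinid = 0.10,
                                           non_commelinid_monocot = 0.35,
                                           non_monocot = 0.70),
                       outgroup_counts = c(non_grass_commelinid = 2,
                                           non_commelinid_monocot = 1,
                                           non_monocot = 3),
                       mean_peptide_length = 300,
                       duplication_identity = 0.85,
                       label_weights = c(non_specific = 0.5,
                                         grass_specific = 0.25,
                                         commelinid_specific = 0.15,
                                         monocot_specific = 0.10),
                       confidence_downgrade = 0.05,
                       row_dropout = 0.02,
                       n_background_outgroup = 10,
                       holdout_divergence = 0.10,
                       n_holdout = 1) {
  stopifnot(n_ingroup_species >= 4,
            substitution_rate >= 0, indel_rate >= 0,
            annotation_dropout_fraction >= 0,
            annotation_dropout_fraction < 1,
            length(outgroup_depths) == 3,
            all(diff(outgroup_depths) > 0),
            duplication_identity > 0.5, duplication_identity < 1,
            n_duplicated_families <= n_universal_families)
  cfg <- list(seed = as.integer(seed),
              n_ingroup_species = n_ingroup_species,
              n_universal_families = n_universal_families,
              n_decoy_families = n_decoy_families,
              n_duplicated_families = n_duplicated_families,
              substitution_rate = substitution_rate,
              indel_rate = indel_rate,
              indel_mean_len = indel_mean_len,
              splice_variant_prob = splice_variant_prob,
              annotation_dropout_fraction = annotation_dropout_fraction,
              outgroup_depths = outgroup_depths,
              outgroup_counts = outgroup_counts,
              mean_peptide_length = mean_peptide_length,
              duplication_identity = duplication_identity,
              label_weights = label_weights / sum(label_weights),
              confidence_downgrade = confidence_downgrade,
              row_dropout = row_dropout,
              n_background_outgroup = n_background_outgroup,
              holdout_divergence = holdout_divergence,
              n_holdout = n_holdout)
  class(cfg) <- "sim_config"
  cfg
}
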