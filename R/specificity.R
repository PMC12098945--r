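# Taxon-specificity: score outgroup peptides against group profiles,
# compute the specificity statistic S at three taxonomic depths, classify
# groups, and run the cutoff-calibration sweep.

OG_LEVELS <- c("non_monocot", "non_commelinid_monocot",
               "non_grass_commelinid")
SPEC_LABELS <- c("non_specific", "monocot_specific",
                 "commelinid_specific", "grass_specific")

#' Assemble an outgroup panel
#'
#' @param pep_sets named list (by species) of `species_pep_set`s.
#' @param levels named character vector: species -> one of
#'   `"non_monocot"`, `"non_commelinid_monocot"`,
#'   `"non_grass_commelinid"`.
#' @return an `outgroup_panel` list.
#' @export
outgroup_panel <- function(pep_sets, levels) {
  stopifnot(all(names(pep_sets) %in% names(levels)),
            all(levels %in% OG_LEVELS))
  structure(list(pep_sets = pep_sets,
                 levels = levels[names(pep_sets)]),
            class = "outgroup_panel")
}

#' Best outgroup R per taxonomic depth
#'
#' For each depth, the maximum R over every peptide of every species at or
#' below that depth (depths nest: the monocot depth uses non-monocot
#' species only; the commelinid depth adds non-commelinid monocots; the
#' grass depth adds non-grass commelinids). Only peptides passing the
#' raw-score hit gate contribute; with no qualifying hit the maximum is 0.
#'
#' @param profile a `profile_model`.
#' @param panel an `outgroup_panel`.
#' @param config a [pipeline_config()].
#' @return named numeric: `monocot`, `commelinid`, `grass` maxima, plus
#'   attribute `best_hits` (per-depth best pep id).
#' @export
best_outgroup_scores <- function(profile, panel,
                                 config = pipeline_config()) {
  if (length(panel$pep_sets) == 0L)
    stopf("best_outgroup_scores: empty outgroup panel")
  best_per_level <- stats::setNames(rep(0, 3), OG_LEVELS)
  best_id_level <- stats::setNames(rep(NA_character_, 3), OG_LEVELS)
  for (sp in names(panel$pep_sets)) {
    lv <- panel$levels[[sp]]
    peps <- panel$pep_sets[[sp]]
    if (nrow(peps) == 0L) next
    raw <- profile_raw_many(profile, peps$sequence)
    ok <- raw >= config$min_raw_bits
    if (!any(ok)) next
    R <- raw[ok] / profile$max_score
    i <- which.max(R)
    if (R[i] > best_per_level[[lv]]) {
      best_per_level[[lv]] <- R[i]
      best_id_level[[lv]] <- peps$pep_id[ok][i]
    }
  }
  out <- c(
    monocot = best_per_level[["non_monocot"]],
    commelinid = max(best_per_level[["non_monocot"]],
                     best_per_level[["non_commelinid_monocot"]]),
    grass = max(best_per_level))
  attr(out, "best_hits") <- best_id_level
  out
}

#' Specificity statistic S at the three depths
#'
#' `S_depth = min_member_R - max_outgroup_R(depth)`. S <= 0 means an
#' outgroup peptide matches the profile as well as the weakest member, so
#' the group is non-specific at that depth by definition.
#'
#' @param group a universal group (with `member_R` filled).
#' @param outgroup_maxima from [best_outgroup_scores()].
#' @return a `specificity_result` list with `group_id`, `min_member_R`,
#'   `max_outgroup_R`, and `S_monocot`, `S_commelinid`, `S_grass`.
#' @export
specificity_scores <- function(group, outgroup_maxima) {
  min_R <- min(unlist(group$member_R))
  structure(list(
    group_id = group$group_id,
    min_member_R = min_R,
    max_outgroup_R = outgroup_maxima,
    S_monocot = min_R - outgroup_maxima[["monocot"]],
    S_commelinid = min_R - outgroup_maxima[["commelinid"]],
    S_grass = min_R - outgroup_maxima[["grass"]],
    label = NA_character_), class = "specificity_result")
}

#' Classify a group's taxon-specificity
#'
#' Deterministic cascade with a strict cutoff: grass-specific if
#' `S_grass > cutoff`; else commelinid-specific if
#' `S_commelinid > cutoff`; else monocot-specific if
#' `S_monocot > cutoff`; else non-specific.
#'
#' @param result a `specificity_result`.
#' @param config a [pipeline_config()].
#' @return the label string.
#' @export
classify_specificity <- function(result, config = pipeline_config()) {
  cut <- config$specificity_cutoff
  if (result$S_grass > cut) "grass_specific"
  else if (result$S_commelinid > cut) "commelinid_specific"
  else if (result$S_monocot > cut) "monocot_specific"
  else "non_specific"
}

#' Specificity table for all universal groups
#'
#' @param gs finalized `group_set`.
#' @param panel an `outgroup_panel`.
#' @param config a [pipeline_config()].
#' @return data.frame: group_id, min_member_R, the three outgroup maxima,
#'   the three S values and the label.
#' @export
specificity_table <- function(gs, panel, config = pipeline_config()) {
  rows <- lapply(universal_groups(gs), function(g) {
    mx <- best_outgroup_scores(g$profile, panel, config)
    res <- specificity_scores(g, mx)
    res$label <- classify_specificity(res, config)
    data.frame(group_id = res$group_id,
               min_member_R = res$min_member_R,
               max_R_monocot = mx[["monocot"]],
               max_R_commelinid = mx[["commelinid"]],
               max_R_grass = mx[["grass"]],
               S_monocot = res$S_monocot,
               S_commelinid = res$S_commelinid,
               S_grass = res$S_grass,
               label = res$label,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(group_id = character(), min_member_R = numeric(),
                      max_R_monocot = numeric(),
                      max_R_commelinid = numeric(),
                      max_R_grass = numeric(), S_monocot = numeric(),
                      S_commelinid = numeric(), S_grass = numeric(),
                      label = character(), stringsAsFactors = FALSE)
  out[order(out$group_id), , drop = FALSE]
}

#' Pairwise-identity baseline for the specificity comparison
#'
#' Percent identity (matches over alignment length) of the group's
#' reference-species member globally aligned to its best-scoring outgroup
#' hit (best R against the group profile among peptides passing the hit
#' gate). Returns `NA` when no outgroup peptide passes the gate.
#'
#' @param group a universal group.
#' @param outgroup_peps a combined `species_pep_set`/data.frame of
#'   outgroup peptides (typically the non-monocot set).
#' @param reference_species which member to align.
#' @param pep_db peptide database.
#' @param config a [pipeline_config()].
#' @return percent identity, or `NA_real_`.
#' @export
pairwise_identity_baseline <- function(group, outgroup_peps,
                                       reference_species, pep_db,
                                       config = pipeline_config()) {
  if (is.null(group$members[[reference_species]]))
    stopf("group %s has no member for %s", group$group_id,
          reference_species)
  ref_seq <- pep_seq(pep_db, group$members[[reference_species]])
  raw <- profile_raw_many(group$profile, outgroup_peps$sequence)
  ok <- raw >= config$min_raw_bits
  if (!any(ok)) return(NA_real_)
  best_seq <- outgroup_peps$sequence[ok][which.max(raw[ok])]
  id <- global_identity(ref_seq, best_seq, config)
  100 * id$matches / id$aln_length
}

#' Sweep specificity cutoffs against labelled test sets
#'
#' For each cutoff: the false positive rate is the fraction of the known
#' non-specific set passing (metric strictly above the cutoff) and the
#' false negative rate is the fraction of the known specific set failing.
#' FP is non-increasing and FN non-decreasing in the cutoff by
#' construction.
#'
#' @param metric_values numeric metric per item.
#' @param labels logical (or "specific"/"non_specific") per item; `TRUE`
#'   means known specific.
#' @param cutoff_grid cutoffs to sweep.
#' @return data.frame with `cutoff`, `false_positive_rate`,
#'   `false_negative_rate`.
#' @export
evaluate_cutoffs <- function(metric_values, labels, cutoff_grid) {
  if (is.character(labels)) labels <- labels == "specific"
  stopifnot(length(metric_values) == length(labels))
  if (!any(labels) || all(labels))
    stopf("evaluate_cutoffs: both labelled sets must be non-empty")
  pos <- metric_values[labels]
  neg <- metric_values[!labels]
  data.frame(
    cutoff = cutoff_grid,
    false_positive_rate = vapply(cutoff_grid,
                                 function(ct) mean(neg > ct), 0),
    false_negative_rate = vapply(cutoff_grid,
                                 function(ct) mean(pos <= ct), 0))
}
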