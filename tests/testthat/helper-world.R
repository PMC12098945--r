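# Shared simulated worlds and pipeline runs, built lazily and cached for
# the whole test session. The default world is the stated one: 8 species,
# 30 universal + 10 decoy + 2 duplicated families, 10% annotation dropout,
# seed 42.

.ug_cache <- new.env(parent = emptyenv())

ug_world <- function() {
  if (!is.null(.ug_cache$world)) return(.ug_cache$world)
  dirA <- file.path(tempdir(), "ug_world_dropout")
  dirB <- file.path(tempdir(), "ug_world_nodropout")
  simA <- simulate_dataset(sim_config(seed = 42), dirA)
  cfg0 <- sim_config(seed = 42)
  cfg0$annotation_dropout_fraction <- 0
  simB <- simulate_dataset(cfg0, dirB)
  .ug_cache$world <- list(simA = simA, simB = simB,
                          dirA = dirA, dirB = dirB)
  .ug_cache$world
}

ug_runA <- function() {
  if (!is.null(.ug_cache$runA)) return(.ug_cache$runA)
  w <- ug_world()
  .ug_cache$runA <- run_pipeline(
    file.path(w$dirA, "pipeline.cfg"),
    out_dir = file.path(w$dirA, "results"), quiet = TRUE)
  .ug_cache$runA
}

ug_runB <- function() {
  if (!is.null(.ug_cache$runB)) return(.ug_cache$runB)
  w <- ug_world()
  .ug_cache$runB <- run_pipeline(
    file.path(w$dirB, "pipeline.cfg"),
    out_dir = file.path(w$dirB, "results"), quiet = TRUE)
  .ug_cache$runB
}

# map each recovered universal group to the planted family owning the
# majority of its members
ug_group_families <- function(run, truth) {
  mem <- read.delim(file.path(run$out_dir, "membership.tsv"))
  fam_of_pep <- stats::setNames(truth$family_id, truth$pep_id)
  vapply(split(mem, mem$group_id), function(g) {
    fams <- stats::na.omit(fam_of_pep[g$pep_id])
    names(sort(table(fams), decreasing = TRUE))[1]
  }, "")
}

# species -> member-sequence signature per group (rescued members compare
# by sequence, so a perfect rescue equals the planted peptide)
ug_group_signatures <- function(run) {
  mem <- read.delim(file.path(run$out_dir, "membership.tsv"))
  db <- run$pep_db
  vapply(split(mem, mem$group_id), function(g) {
    paste(g$species, db$sequence[match(g$pep_id, db$pep_id)],
          collapse = "|")
  }, "")
}

# the planted signature of a family, from the no-dropout world
ug_truth_signature <- function(family, truth, dbB) {
  t <- truth[truth$family_id == family, ]
  t <- t[order(t$species), ]
  paste(t$species, dbB$sequence[match(t$pep_id, dbB$pep_id)],
        collapse = "|")
}

# two groups built directly from a planted family and its duplicate
# evolved to a target member identity (supergroup scenarios)
ug_duplicate_pair <- function(identity_target, seed = 42,
                              family = "fam001",
                              config = pipeline_config()) {
  w <- ug_world()
  db <- ug_runA()$pep_db
  truth <- w$simA$truth
  set.seed(seed)
  fam <- truth[truth$family_id == family, ]
  seqs <- stats::setNames(db$sequence[match(fam$pep_id, db$pep_id)],
                          fam$species)
  seqs <- seqs[!is.na(seqs)]
  dup <- plant_duplication(seqs, identity_target)
  db2 <- mini_db_from(c(stats::setNames(unname(seqs),
                                        paste0("A_", names(seqs))),
                        stats::setNames(unname(dup),
                                        paste0("B_", names(dup)))),
                      rep(names(seqs), 2))
  gA <- mk_universal_group("A", seqs, db2, config)
  gB <- mk_universal_group("B", dup, db2, config)
  gs <- structure(list(groups = list(A = gA, B = gB),
                       species = sort(names(seqs))),
                  class = "group_set")
  list(gs = gs, db = db2, seqs = seqs, dup = dup)
}

mini_db_from <- function(named_seqs, species) {
  db <- data.frame(pep_id = names(named_seqs), gene_id = names(named_seqs),
                   species = species, sequence = unname(named_seqs),
                   source = "annotated", stringsAsFactors = FALSE)
  rownames(db) <- db$pep_id
  class(db) <- c("pep_db", "data.frame")
  db
}
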