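# Unit tests against small constructed worlds (the end-to-end behaviour on
# the simulated world is covered in test-pipeline.R and test-acceptance.R).

# build a minimal two-reference world: refs r1/r2, targets t1/t2
tiny_world <- function() {
  set.seed(61)
  anc1 <- rand_seq(50); anc2 <- rand_seq(50)
  mk <- function(anc, d) evolve_sequence(anc, d)
  db <- mini_db(
    list("r1_a_t1", "r1_a", "r1", anc1),
    list("r1_b_t1", "r1_b", "r1", anc2),
    list("r2_a_t1", "r2_a", "r2", mk(anc1, 0.05)),
    list("r2_b_t1", "r2_b", "r2", mk(anc2, 0.05)),
    list("t1_a_t1", "t1_a", "t1", mk(anc1, 0.1)),
    list("t1_b_t1", "t1_b", "t1", mk(anc2, 0.1)),
    list("t2_a_t1", "t2_a", "t2", mk(anc1, 0.1)),
    list("t2_b_t1", "t2_b", "t2", mk(anc2, 0.1)))
  ot <- function(ref, rows) {
    df <- do.call(rbind, lapply(rows, function(r)
      data.frame(ref_gene = r[[1]], target_species = r[[2]],
                 target_gene = r[[3]], confidence = r[[4]],
                 stringsAsFactors = FALSE)))
    attr(df, "reference_species") <- ref
    class(df) <- c("ortholog_table", "data.frame")
    df
  }
  t1 <- ot("r1", list(
    list("r1_a", "r2", "r2_a", 1L), list("r1_a", "t1", "t1_a", 1L),
    list("r1_a", "t2", "t2_a", 1L),
    list("r1_b", "r2", "r2_b", 1L), list("r1_b", "t1", "t1_b", 1L),
    list("r1_b", "t2", "t2_b", 1L)))
  t2 <- ot("r2", list(
    list("r2_a", "r1", "r1_a", 1L), list("r2_a", "t1", "t1_a", 1L),
    list("r2_a", "t2", "t2_a", 1L),
    list("r2_b", "r1", "r1_b", 1L), list("r2_b", "t1", "t1_b", 1L),
    list("r2_b", "t2", "t2_b", 1L)))
  list(db = db, t1 = t1, t2 = t2)
}

test_that("seed_groups links the two references through orthology", {
  w <- tiny_world()
  gs <- seed_groups(list(w$t1, w$t2), NULL, w$db)
  expect_equal(length(gs$groups), 2L)
  for (g in gs$groups) expect_equal(g$status, "seeded")
  lk <- gs$links
  # each group has candidates in all four species
  for (gid in names(gs$groups))
    expect_setequal(unique(lk$species[lk$group_id == gid]),
                    c("r1", "r2", "t1", "t2"))
})

test_that("maize-style merge rules: best hit honored only when not orthologous elsewhere", {
  w <- tiny_world()
  # remove the r1_a -> r2 ortholog row: the best second-reference hit is
  # r2_a, which is orthologous back to r1_a only -> composite merge
  t1 <- w$t1[!(w$t1$ref_gene == "r1_a" & w$t1$target_species == "r2"), ]
  attr(t1, "reference_species") <- "r1"
  class(t1) <- class(w$t1)
  gs <- seed_groups(list(t1, w$t2), NULL, w$db)
  gid <- grep("\\+", names(gs$groups), value = TRUE)
  expect_equal(length(gid), 1L)
  lk <- gs$links
  expect_true("r2_a_t1" %in% lk$pep_id[lk$group_id == gid])

  # now point r2_a's back-orthology at a different gene: no merge, and the
  # unlinked second-reference cluster seeds its own group
  t2 <- w$t2
  t2$target_gene[t2$ref_gene == "r2_a" & t2$target_species == "r1"] <-
    "r1_b"
  attr(t2, "reference_species") <- "r2"
  gs <- seed_groups(list(t1, t2), NULL, w$db)
  expect_false(any(grepl("\\+", names(gs$groups))))
  expect_true(any(grepl("^r2:", names(gs$groups))))
})

test_that("assign_exclusive ranks by confidence, then similarity, then id", {
  w <- tiny_world()
  gs <- seed_groups(list(w$t1, w$t2), NULL, w$db)
  # plant one pep as candidate of both groups with differing confidence
  extra <- gs$links[gs$links$pep_id == "t1_a_t1", ][1, ]
  other <- setdiff(names(gs$groups), extra$group_id)[1]
  dup_row <- extra; dup_row$group_id <- other; dup_row$confidence <- 0L
  gs$links <- rbind(gs$links, dup_row)
  gs <- assign_exclusive(gs)
  got <- gs$assigned[gs$assigned$pep_id == "t1_a_t1", ]
  expect_equal(nrow(got), 1L)
  expect_equal(got$group_id, extra$group_id)  # confidence 1 wins

  # equal confidence: higher similarity wins
  gs2 <- seed_groups(list(w$t1, w$t2), NULL, w$db)
  lk <- gs2$links
  r <- lk[lk$pep_id == "t1_a_t1", ][1, ]
  dup_row <- r; dup_row$group_id <- setdiff(names(gs2$groups),
                                            r$group_id)[1]
  dup_row$similarity <- r$similarity - 5
  gs2$links <- rbind(gs2$links, dup_row)
  gs2 <- assign_exclusive(gs2)
  expect_equal(gs2$assigned$group_id[gs2$assigned$pep_id == "t1_a_t1"],
               r$group_id)

  # full tie: lexicographically smaller group id
  gs3 <- seed_groups(list(w$t1, w$t2), NULL, w$db)
  r <- gs3$links[gs3$links$pep_id == "t1_a_t1", ][1, ]
  dup_row <- r
  dup_row$group_id <- setdiff(names(gs3$groups), r$group_id)[1]
  gs3$links <- rbind(gs3$links, dup_row)
  gs3 <- assign_exclusive(gs3)
  expect_equal(gs3$assigned$group_id[gs3$assigned$pep_id == "t1_a_t1"],
               min(r$group_id, dup_row$group_id))
})

test_that("prune_sparse applies the coverage boundary and reassigns", {
  # 16-species world: 11 covered -> deleted, 12 covered -> retained
  sp16 <- sprintf("s%02d", 1:16)
  mk_links <- function(gid, n_cov) {
    data.frame(group_id = gid, species = sp16[seq_len(n_cov)],
               pep_id = paste0(gid, "_", sp16[seq_len(n_cov)]),
               gene_id = paste0(gid, "_g"), confidence = 1L,
               similarity = 50, stringsAsFactors = FALSE)
  }
  g <- function(id) list(group_id = id, members = list(),
                         member_R = list(), n_rescued = 0L,
                         status = "seeded", reason = NA_character_)
  gs <- structure(list(
    groups = list(G11 = g("G11"), G12 = g("G12")),
    links = rbind(mk_links("G11", 11), mk_links("G12", 12)),
    species = sp16), class = "group_set")
  cfg <- pipeline_config()
  gs <- prune_sparse(gs, cfg)
  expect_equal(gs$groups$G11$status, "discarded")
  expect_equal(gs$groups$G11$reason, "sparse")
  expect_equal(gs$groups$G12$status, "seeded")

  # a deleted group's pep re-attachable elsewhere is reassigned there
  lk2 <- rbind(mk_links("G11", 11), mk_links("G12", 12))
  extra <- lk2[lk2$group_id == "G11" & lk2$species == "s01", ]
  extra$group_id <- "G12"
  lk2 <- rbind(lk2, extra)   # pep G11_s01 is candidate of both
  gs <- structure(list(
    groups = list(G11 = g("G11"), G12 = g("G12")),
    links = lk2, species = sp16), class = "group_set")
  gs <- assign_exclusive(gs, cfg)
  # before pruning the duplicate sits in G11 (smaller id on tie)
  expect_equal(gs$assigned$group_id[gs$assigned$pep_id == "G11_s01"],
               "G11")
  gs <- prune_sparse(gs, cfg)
  expect_equal(gs$groups$G11$status, "discarded")
  expect_equal(gs$assigned$group_id[gs$assigned$pep_id == "G11_s01"],
               "G12")
})

test_that("optimize_group: fixpoint on identical candidates; delta rule", {
  set.seed(62)
  sp <- c("s1", "s2", "s3", "s4", "s5", "s6", "s7", "s8")
  cons <- rand_seq(200)
  mut <- function(s, n) {
    ch <- strsplit(s, "")[[1]]
    pos <- sample(length(ch), n)
    for (p in pos) ch[p] <- setdiff(AA, ch[p])[1]
    paste(ch, collapse = "")
  }
  # identical candidates -> zero substitutions
  db <- mini_db_from(stats::setNames(rep(cons, 8), paste0("p_", sp)), sp)
  cand <- data.frame(group_id = "G", species = sp,
                     pep_id = paste0("p_", sp), gene_id = paste0("g", sp),
                     confidence = 1L, similarity = 100,
                     stringsAsFactors = FALSE)
  g <- list(group_id = "G", members = list(), member_R = list(),
            n_rescued = 0L, status = "seeded", reason = NA,
            candidates = cand)
  cfg <- pipeline_config()
  og <- optimize_group(g, cfg, db, sp)
  expect_equal(og$status, "optimized")
  expect_null(og$substitutions)
  expect_equal(min(unlist(og$member_R)), 1, tolerance = 1e-9)

  # s8's top-ranked candidate is heavily truncated; the full-length
  # alternative improves R by far more than 0.01 -> substituted
  trunc <- substr(cons, 1, 120)
  full <- cons
  db2 <- mini_db_from(c(stats::setNames(rep(cons, 7), paste0("p_", sp[1:7])),
                        p_trunc = trunc, p_full = full),
                      c(sp[1:7], "s8", "s8"))
  cand2 <- rbind(cand[cand$species != "s8", ],
                 data.frame(group_id = "G", species = "s8",
                            pep_id = c("p_trunc", "p_full"),
                            gene_id = "g8", confidence = c(1L, 0L),
                            similarity = c(60, 100),
                            stringsAsFactors = FALSE))
  g2 <- g; g2$candidates <- cand2
  og2 <- optimize_group(g2, cfg, db2, sp)
  expect_equal(og2$members$s8, "p_full")
  expect_equal(nrow(og2$substitutions), 1L)
  expect_gt(og2$substitutions$delta_R, 0.01)

  # small improvement (0 < dR <= 0.01) is rejected: member has 4
  # mutations, alternative has 1; with the member's own residues inside
  # the profile the net gain is a few bits against a ~800-bit maximum
  memb <- mut(cons, 4); alt <- mut(cons, 1)
  db3 <- mini_db_from(c(stats::setNames(rep(cons, 7), paste0("p_", sp[1:7])),
                        p_memb = memb, p_alt = alt),
                      c(sp[1:7], "s8", "s8"))
  cand3 <- rbind(cand[cand$species != "s8", ],
                 data.frame(group_id = "G", species = "s8",
                            pep_id = c("p_memb", "p_alt"),
                            gene_id = "g8", confidence = c(1L, 0L),
                            similarity = c(99, 99.5),
                            stringsAsFactors = FALSE))
  g3 <- g; g3$candidates <- cand3
  og3 <- optimize_group(g3, cfg, db3, sp)
  # oracle: evaluate both choices directly against the initial profile
  prof <- og3$profile
  dR <- score_profile(prof, alt)$R - score_profile(prof, memb)$R
  expect_gt(dR, 0)
  expect_lte(dR, 0.01)
  expect_equal(og3$members$s8, "p_memb")  # rejected
  expect_null(og3$substitutions)
})

test_that("rescue_from_unassigned fills holes and respects exclusivity", {
  set.seed(63)
  sp <- paste0("s", 1:8)
  cons <- rand_seq(150)
  seqs <- stats::setNames(
    vapply(1:7, function(i) evolve_sequence(cons, 0.03), ""), sp[1:7])
  hole_seq <- evolve_sequence(cons, 0.03)   # true member, unassigned
  junk <- rand_seq(150)
  db <- mini_db_from(c(stats::setNames(unname(seqs), paste0("p_", sp[1:7])),
                       p_hole = hole_seq, p_junk = junk),
                     c(sp[1:7], "s8", "s8"))
  g <- mk_universal_group("G", seqs, db)
  g$status <- "optimized"
  gs <- structure(list(groups = list(G = g), species = sp),
                  class = "group_set")
  cfg <- pipeline_config()
  gs2 <- rescue_from_unassigned(gs, db, cfg, sp)
  expect_equal(gs2$groups$G$members$s8, "p_hole")

  # a pep already a member elsewhere is never offered
  g_other <- mk_universal_group(
    "H", stats::setNames(hole_seq, "s8"),
    db)
  g_other$status <- "optimized"
  g_fresh <- mk_universal_group("G", seqs, db); g_fresh$status <- "optimized"
  gs3 <- structure(list(groups = list(G = g_fresh, H = g_other),
                        species = sp), class = "group_set")
  gs3 <- rescue_from_unassigned(gs3, db, cfg, sp)
  expect_null(gs3$groups$G$members$s8)
})

test_that("finalize_universal applies both discard rules", {
  set.seed(64)
  sp <- paste0("s", 1:4)
  cons <- rand_seq(100)
  seqs <- stats::setNames(vapply(1:4, function(i)
    evolve_sequence(cons, 0.05), ""), sp)
  db <- mini_db_from(stats::setNames(unname(seqs), paste0("p_", sp)), sp)
  cfg <- pipeline_config()
  g_full <- mk_universal_group("G", seqs, db); g_full$status <- "optimized"
  g_miss <- mk_universal_group("H", seqs[1:3], db)
  g_miss$status <- "optimized"
  gs <- structure(list(groups = list(G = g_full, H = g_miss),
                       species = sp), class = "group_set")
  gs <- finalize_universal(gs, cfg, db, sp)
  expect_equal(gs$groups$G$status, "universal")
  expect_gte(gs$groups$G$min_R, 0.65)
  expect_equal(gs$groups$H$status, "discarded")
  expect_equal(gs$groups$H$reason, "missing_species")

  # low-R discard: corrupt one member with an unrelated sequence
  db2 <- rbind(db, mini_db(list("p_bad", "gb", "s4", rand_seq(100))))
  class(db2) <- class(db)
  g_bad <- g_full
  g_bad$members$s4 <- "p_bad"
  g_bad$status <- "optimized"
  gs2 <- structure(list(groups = list(G = g_bad), species = sp),
                   class = "group_set")
  gs2 <- finalize_universal(gs2, cfg, db2, sp)
  expect_equal(gs2$groups$G$status, "discarded")
  expect_equal(gs2$groups$G$reason, "low_R")
})

test_that("membership exclusivity holds on the simulated world", {
  run <- ug_runA()
  mem <- read.delim(file.path(run$out_dir, "membership.tsv"))
  expect_equal(anyDuplicated(mem$pep_id), 0L)
  # every universal group has exactly one member per species
  tab <- table(mem$group_id, mem$species)
  expect_true(all(tab == 1L))
})
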