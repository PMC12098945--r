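mk_panel <- function(..., levels) {
  sets <- list(...)
  outgroup_panel(sets, levels)
}

test_that("best_outgroup_scores nests depths and honors the hit gate", {
  set.seed(81)
  cfg <- pipeline_config()
  cons <- rand_seq(80)
  p <- build_profile(build_msa(rep(cons, 4)), cfg)
  near <- evolve_sequence(cons, 0.15)
  far <- evolve_sequence(cons, 0.60)
  ps <- function(id, seq, sp) new_pep_set(pep_id = id, gene_id = id,
                                          species = sp, sequence = seq)
  panel <- mk_panel(
    og1 = ps("x1", cons, "og1"),            # the consensus itself
    og2 = ps("x2", near, "og2"),
    og3 = ps("x3", far, "og3"),
    levels = c(og1 = "non_monocot", og2 = "non_commelinid_monocot",
               og3 = "non_grass_commelinid"))
  mx <- best_outgroup_scores(p, panel, cfg)
  expect_equal(mx[["monocot"]], 1, tolerance = 1e-9)
  expect_true(mx[["grass"]] >= mx[["commelinid"]],
              mx[["commelinid"]] >= mx[["monocot"]])

  # planted ortholog at 15% vs 60% divergence: shallower scores higher
  expect_gt(score_profile(p, near)$R, score_profile(p, far)$R)

  # empty peptide sets -> all maxima 0
  empty <- new_pep_set()
  panel0 <- mk_panel(og1 = empty, og2 = empty, og3 = empty,
                     levels = c(og1 = "non_monocot",
                                og2 = "non_commelinid_monocot",
                                og3 = "non_grass_commelinid"))
  mx0 <- best_outgroup_scores(p, panel0, cfg)
  expect_true(all(mx0 == 0))
  expect_error(best_outgroup_scores(p, outgroup_panel(list(),
                                                      character(0)), cfg),
               "empty outgroup panel")
})

test_that("S arithmetic and the no-hit convention", {
  g <- list(group_id = "G", member_R = list(a = 0.95, b = 0.97))
  mx <- c(monocot = 0.60, commelinid = 0.60, grass = 0.60)
  res <- specificity_scores(g, mx)
  expect_equal(res$S_monocot, 0.35)
  expect_equal(res$min_member_R, 0.95)

  # outgroup at least as good as the weakest member -> S <= 0
  mx2 <- c(monocot = 0.96, commelinid = 0.96, grass = 0.96)
  expect_lte(specificity_scores(g, mx2)$S_monocot, 0)

  # no outgroup hit at any depth -> S equals min member R
  mx3 <- c(monocot = 0, commelinid = 0, grass = 0)
  expect_equal(specificity_scores(g, mx3)$S_grass, 0.95)
})

test_that("classification cascade with strict cutoff", {
  cfg <- pipeline_config()
  mk <- function(sm, sc, sg)
    list(S_monocot = sm, S_commelinid = sc, S_grass = sg)
  expect_equal(classify_specificity(mk(0.40, 0.30, 0.05), cfg),
               "commelinid_specific")
  expect_equal(classify_specificity(mk(0.25, 0.1, 0.0), cfg),
               "non_specific")           # exactly at cutoff: strict >
  expect_equal(classify_specificity(mk(0.9, 0.8, 0.5), cfg),
               "grass_specific")
  expect_equal(classify_specificity(mk(0.3, 0.2, 0.1), cfg),
               "monocot_specific")
})

test_that("pairwise identity baseline", {
  set.seed(82)
  cfg <- pipeline_config()
  sp <- paste0("s", 1:4)
  cons <- rand_seq(100)
  seqs <- stats::setNames(vapply(1:4, function(i)
    evolve_sequence(cons, 0.03), ""), sp)
  db <- mini_db_from(stats::setNames(unname(seqs), paste0("p_", sp)), sp)
  g <- mk_universal_group("G", seqs, db)
  # outgroup containing the reference member itself -> 100%
  og <- new_pep_set(pep_id = "o1", gene_id = "o1", species = "og",
                    sequence = unname(seqs["s1"]))
  expect_equal(pairwise_identity_baseline(g, og, "s1", db, cfg), 100)
  # no hit passes the gate -> absent marker
  og0 <- new_pep_set(pep_id = "o2", gene_id = "o2", species = "og",
                     sequence = rand_seq(90))
  expect_true(is.na(pairwise_identity_baseline(g, og0, "s1", db, cfg)))
  # planted ~75%-identical hit
  div <- evolve_sequence(cons, -log(0.75))
  og2 <- new_pep_set(pep_id = "o3", gene_id = "o3", species = "og",
                     sequence = div)
  v <- pairwise_identity_baseline(g, og2, "s1", db, cfg)
  id <- global_identity(unname(seqs["s1"]), div, cfg)
  expect_equal(v, 100 * id$matches / id$aln_length, tolerance = 1e-9)
  expect_gt(v, 60); expect_lt(v, 90)
})

test_that("evaluate_cutoffs sweeps FP/FN monotonically", {
  # perfectly separated sets: some cutoff reaches FP = FN = 0
  spec <- c(0.8, 0.9, 0.7); nons <- c(0.1, 0.2, 0.3)
  ec <- evaluate_cutoffs(c(spec, nons),
                         c(rep(TRUE, 3), rep(FALSE, 3)),
                         seq(0, 1, by = 0.05))
  expect_true(any(ec$false_positive_rate == 0 &
                  ec$false_negative_rate == 0))
  # cutoff below all values: FP = 1, FN = 0
  expect_equal(ec$false_positive_rate[1], 1)
  expect_equal(ec$false_negative_rate[1], 0)
  expect_true(all(diff(ec$false_positive_rate) <= 0))
  expect_true(all(diff(ec$false_negative_rate) >= 0))
  expect_error(evaluate_cutoffs(1:3, c(TRUE, TRUE, TRUE), 0.5),
               "non-empty")

  # planted overlap fraction 0.1: brute force over all thresholds finds
  # min(FP+FN) <= 0.1
  set.seed(83)
  spec <- c(runif(95, 0.5, 1), runif(5, 0, 0.5))
  nons <- c(runif(95, 0, 0.5), runif(5, 0.5, 1))
  grid <- sort(unique(c(spec, nons, 0.5)))
  ec <- evaluate_cutoffs(c(spec, nons),
                         c(rep(TRUE, 100), rep(FALSE, 100)), grid)
  # independent oracle: direct counting at every threshold
  best <- min(vapply(grid, function(ct)
    mean(nons > ct) + mean(spec <= ct), 0))
  expect_lte(best, 0.1)
  expect_equal(min(ec$false_positive_rate + ec$false_negative_rate), best,
               tolerance = 1e-12)
})

test_that("specificity table on the simulated world partitions and nests", {
  run <- ug_runA()
  spec <- run$specificity
  expect_equal(nrow(spec), run$manifest$n_groups_universal)
  expect_true(all(spec$label %in% c("non_specific", "monocot_specific",
                                    "commelinid_specific",
                                    "grass_specific")))
  expect_true(all(spec$S_grass <= spec$S_commelinid + 1e-9))
  expect_true(all(spec$S_commelinid <= spec$S_monocot + 1e-9))
})
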