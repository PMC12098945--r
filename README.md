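# univgroups

Identify **universal groups** of highly conserved protein-coding genes
across a clade — groups with exactly one member per species, present in
*every* species — from per-species peptide sets and ortholog tables, and
grade how taxon-specific each group is.

The package is aimed at comparative genomicists working with a focal clade
(the motivating case is the core grasses, spanned by two well-annotated
reference lineages) who want a database of one-per-species conserved genes
that can anchor cross-species function transfer, plus an explicit measure
of which of those genes are private to the clade.

## The method in brief

1. **Seeding.** Reference-species peptides are deduplicated, collapsed
   into clusters (>90% identity in both directions, complete linkage),
   and each cluster seeds a candidate group. The second reference is
   merged through its ortholog link (or a best-similarity hit when it is
   not orthologous to any other first-reference gene); candidates for all
   other species are the union of orthologs of both references. Each
   peptide is assigned exclusively to one group, ranked by ortholog
   confidence flag then sequence similarity. Groups covering fewer than
   3/4 of the species are deleted and their candidates reassigned.
2. **Optimization.** Each group is reduced to one peptide per species: a
   profile model is built from the members' multiple alignment and a
   candidate substitution is kept only if it improves the member's
   relative score by more than 0.01. The relative score of a query is

   *R* = (profile alignment score of the query) / (score of the profile's
   consensus sequence),

   so *R* = 1 means consensus-perfect and *R* is comparable across groups
   of different lengths and conservation levels.
3. **Rescue.** Unassigned peptides that hit a profile, and novel gene
   models found in genomic sequence with the group consensus as query
   (single-exon six-frame ORF stub built in; external gene finders plug in
   through an adapter), can fill missing members under the same
   improvement rule — at most 4 rescued members per group, and the
   annotated-member floor is never violated.
4. **Universality filter.** A group is universal iff every species has a
   member and the lowest-scoring member has *R* ≥ 0.65.
5. **Specificity.** Outgroup peptides at three taxonomic depths are scored
   against each profile. The specificity statistic at a depth is

   *S* = min member *R* − max outgroup *R*,

   and a group is classified grass-/commelinid-/monocot-specific by a
   strict cascade at *S* > 0.25 (deepest depth first); *S* ≤ 0 means an
   outgroup peptide matches as well as the weakest member.
6. **Screening.** Non-members with *R* > 0.65 to a group become
   *associates* (many-to-many); groups whose members all mutually score
   *R* > 0.65 against each other's profiles form *supergroups*; external
   proteomes/genomes are matched per group for validation.

A fully deterministic simulator (`simulate_dataset()`) generates
truth-labelled peptide sets, ortholog tables, genomes + GFF3 annotations
with controlled annotation dropout, and outgroup panels, so the entire
pipeline is testable offline.

## Worked example

```r
library(univgroups)
sim <- simulate_dataset(sim_config(seed = 1, n_ingroup_species = 4,
                                   n_universal_families = 6,
                                   n_decoy_families = 2,
                                   n_duplicated_families = 1,
                                   mean_peptide_length = 150),
                        "demo")
res <- run_pipeline("demo/pipeline.cfg")
head(read.delim(file.path(res$out_dir, "membership.tsv")))
```

```
    group_id species         pep_id    source         R
1 sp01:R0001    sp01 sp01_fam001_t1 annotated 0.9950970
2 sp01:R0001    sp02 sp02_fam001_t1 annotated 0.9811557
3 sp01:R0001    sp03 sp03_fam001_t1 annotated 0.9789107
4 sp01:R0001    sp04 sp04_fam001_t1 annotated 0.9649694
5 sp01:R0002    sp01 sp01_fam002_t1 annotated 0.9710158
6 sp01:R0002    sp02 sp02_fam002_t1 annotated 0.9742790
```

Every universal group has one member per species; `R` is each member's
relative score against the final group profile (all well above the 0.65
universality cutoff here).

```r
res$specificity[, c("group_id", "min_member_R", "S_monocot", "S_grass",
                    "label")]
```

```
    group_id min_member_R  S_monocot    S_grass               label
1 sp01:R0001    0.9649694 0.05104410 0.05104410        non_specific
2 sp01:R0002    0.9710158 0.06833913 0.06833913        non_specific
3 sp01:R0003    0.9546745 0.01420246 0.01420246        non_specific
4 sp01:R0004    0.9705807 0.97058071 0.97058071      grass_specific
5 sp01:R0005    0.9715361 0.97153607 0.06368901 commelinid_specific
6 sp01:R0006    0.9826986 0.98269862 0.09755074    monocot_specific
```

Group `R0001` has a close outgroup match at every depth (*S* ≈ 0.05, not
above the 0.25 cutoff anywhere): non-specific. `R0004` has no outgroup
match at all (*S* = min member *R* at every depth): grass-specific.
`R0005` is matched only by the nearest outgroup ring, so it clears the
cutoff at the commelinid depth but not the grass depth.

The same stages are available as a CLI:

```sh
Rscript -e 'univgroups::univgroups_cli()' simulate --seed 42 --out world
Rscript -e 'univgroups::univgroups_cli()' run --config world/pipeline.cfg
```

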