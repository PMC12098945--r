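---
title: "univgroups: methods, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{univgroups: methods, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The problem

Across a clade of related genomes, a core of protein-coding genes is so
conserved that one representative per species can be treated as carrying a
common function. Building that core set well is harder than it sounds:
annotations disagree on splice variants, gene models are missing from
newly sequenced genomes, ortholog tables are incomplete, and paralogs from
old duplications compete for membership. `univgroups` implements a
complete pipeline that (i) assembles candidate groups from the ortholog
tables of two reference species, (ii) optimizes each group to exactly one
member per species by profile score, (iii) rescues missing members from
genomic sequence, and (iv) grades each group's taxon-specificity against
outgroup proteomes at three phylogenetic depths.

# The profile model and the relative score R

Group members are aligned with a deterministic progressive aligner
(affine gaps, BLOSUM62 column scores; sequences are added in input order
to a growing profile, so identical inputs always give identical
alignments). Alignment columns with non-gap occupancy ≥ 0.5 (inclusive)
become match states. Emission probabilities use a single pseudocount with
a uniform background:

$$e_k(a) = \frac{c_k(a) + \alpha q_a}{n_k + \alpha},\qquad
  m_k(a) = \log_2 \frac{e_k(a)}{q_a},\qquad
  \alpha = 1,\; q_a = 1/20 .$$

A query is scored by a Viterbi alignment that is global in both the
profile and the query: skipping a match state costs 2 bits, an inserted
run costs 3 bits to open and 1 bit per additional residue (zero insert
emission), and `X` emits 0 bits anywhere. The maximum attainable score is
$\sum_k \max_a m_k(a)$, realized exactly by the consensus (per-state
argmax, alphabetical tie-break), so the relative score

$$R = \frac{\text{raw}}{\text{max score}}$$

satisfies $R \le 1$ for every sequence and $R(\text{consensus}) = 1$
identically. Because insert emissions are never positive and penalties are
subtracted, no path can exceed the consensus path; the test suite checks
this against exhaustive path enumeration for all small profiles and
against 1000 random queries × 50 random profiles.

Choices worth knowing about:

* **Uniform background** rather than empirical amino-acid frequencies
  removes a data dependency; it slightly flattens log-odds but cancels in
  the R ratio to first order.
* **Uniform sequence weighting** (no Henikoff weighting); every row
  counts fully, and no row is down-weighted as a fragment.
* **Penalties** (2/3/1 bits) are configuration values. They were chosen
  so that a single deletion in an otherwise perfect query of a 20-state
  profile keeps R > 0.65 (asserted in the tests): deletions reflect
  annotation artifacts more often than function change at this scale.
* **Degenerate-profile guard**: profiles with max score < 1 bit are
  rejected.
* The scorer is this package's own (an HMMER-style engine can be swapped
  in behind the rescue adapter); R is a ratio and is robust to the
  backend, but absolute bit scores are not comparable to HMMER's.

# Group building

* **Clustering**: reference peptides are collapsed at >90% identity in
  *both* directions (each sequence's own length is the denominator —
  "both directions" rules out alignment-length denominators), complete
  linkage, greedy in input order for determinism. Only each gene's
  primary (first-seen) peptide takes part in clustering; splice variants
  join their gene's candidate pool. This prevents a divergent variant
  from seeding a second group for the same gene.
* **Exclusive assignment** ranks (confidence flag, similarity to the
  group's reference peptide, peptide id); full ties go to the smaller
  group id. "Similarity" is the mean of the two directed global
  identities.
* **Pruning** deletes groups covering < 3/4 of the species (the
  "at most four of sixteen missing" rule generalized) and re-offers their
  candidates to survivors, iterating to a fixpoint.
* **Optimization** evaluates species in a fixed order, rebuilds the
  profile after every accepted substitution (the alternative, once per
  pass, is available via `recompute = "per_pass"`), accepts a
  substitution only when the candidate's R exceeds the member's by more
  than 0.01, and stops at a full no-substitution pass or after
  `max_passes = 5` passes (a convergence guard; the procedure almost
  always fixes in one or two passes).
* The improvement rule compares the *substituted member's* R (the most
  literal reading); the group minimum is recomputed at finalization and
  logged.

# Gene rescue

Missing or low-scoring (R < 0.65) members trigger a genomic search with
the group profile. The built-in adapter is a six-frame single-exon ORF
scan (ATG…stop, ≥ 30 aa) — sufficient for the simulator's genome dialect;
multi-exon gene finding is an adapter concern (`adapter =` argument takes
any `function(genome, query)` returning scored models). A model is
adopted only if it is *novel* — no same-strand exon overlap of ≥ 1 bp
with any annotated exon (exact-exon-set equality is deliberately not the
default; the strictest reading is the safest against double-counting) —
and fills a hole or clears the same ΔR > 0.01 rule. Caps: at most 4
rescued members per group, and the count of annotated members never drops
below ⌈0.75 × n⌉. Holes are processed before low scorers, lowest R first.

# Specificity

Outgroup species are labelled with one of three nested levels
(non-monocot ⊂ non-commelinid ⊂ non-grass, in the motivating clade's
vocabulary). For each universal group, the best outgroup R per depth uses
all species at or below that depth; peptides failing the raw-bit hit gate
(the internal analogue of an E-value threshold, default 10 bits) are
ignored and an empty depth scores 0 — so a group with no outgroup hit at
all has S equal to its minimum member R. Classification is a strict
cascade at S > 0.25: grass first, then commelinid, then monocot, else
non-specific. The cascade resolves "classify by the S of each level" into
a deterministic rule; S values nest (S_grass ≤ S_commelinid ≤ S_monocot)
by construction, which the tests assert globally. With few informative
species at the intermediate levels, sub-level labels are intrinsically
less secure; the per-depth best-hit ids are exposed in the results rather
than a confidence model.

The pairwise-identity baseline (for comparing S against a simpler
statistic) aligns the reference-species member to its best-scoring
outgroup hit and reports matches over *alignment length* — deliberately a
different denominator from the clustering identity, because it mirrors a
global-alignment identity readout. Its direction is inverted relative to
S (lower identity = more specific), so cutoff sweeps feed it negated.

# The simulator: what it emulates, and what it does not

`simulate_dataset()` emits every input the pipeline consumes — peptide
FASTA with splice variants, two ortholog tables with confidence noise
(5% downgrades, 2% dropped rows), single-exon genomes with GFF3
annotations, outgroup panels, a holdout species, and a truth table — as a
pure function of the seed.

* **Ingroup**: a balanced binary tree over `n_ingroup_species` (default
  8); the two references are the first species of each half, mirroring
  two reference lineages spanning the clade. Family roots are random
  peptides (mean length 300, always starting with methionine); members
  evolve per branch at `substitution_rate` (default 0.05
  substitutions/site, i.e. root-to-tip 0.15 and a worst-case pairwise
  distance of 0.30 ≈ 74% identity — realistic for highly conserved genes
  spanning two deep clades). Substitutions replace residues from a fixed
  composition-weighted background, giving expected identity
  ≈ exp(−distance); indels are Poisson events with geometric lengths.
* **Decoys** (default 10) are planted in at most half the species —
  enough to be seeded through a reference, sparse enough to be pruned.
* **Duplicated families** (default 2) are member-level duplicates at 85%
  identity — deliberately below the 90% clustering threshold, because at
  ≥ 90% the two reference copies collapse into one cluster (faithful to
  the clustering rule) and only one group can exist. The supergroup
  dichotomy asserted in acceptance (95% duplicate → one supergroup, 82% →
  two independent groups) is therefore tested at the operation level on
  directly built group pairs. During calibration of `substitution_rate`
  the margin of that dichotomy was checked across several draws: the 82%
  side sits close to the R = 0.65 boundary (cross-scores ≈ 0.58–0.67),
  which is worth knowing if you change the world's divergence.
* **Annotation dropout** removes the GFF3 entry *and* the peptide of 10%
  of planted member genes while leaving the genomic copy intact. The
  budget is a fraction of all member entries but is drawn from
  non-reference species only: a dropped reference member could never be
  rescued (groups are seeded from reference annotations), violating the
  generator's own recoverable-in-principle guarantee — and the reference
  genomes are the well-annotated ones by construction. Dropout is
  weighted 5:1 toward two designated "poorly annotated" species,
  mirroring how rescued gene models concentrate in newly sequenced
  genomes. Dropout uses an isolated RNG stream so dropout and no-dropout
  worlds are otherwise identical — that is what makes the
  restore-and-compare acceptance contrast meaningful.
* **Outgroup copies** follow each family's planted label: a family
  labelled X-specific has copies in every outgroup species inside X's
  boundary and none outside, evolved at the shallow depth (0.10) from the
  family root — "conserved wherever present". Planting copies at the
  level depths (0.35/0.70) instead would make monocot-specific families
  classify as commelinid-specific by arithmetic (min R − R(0.35-copy) ≈
  0.3 > 0.25), so those depths are used as the divergence of decoy-family
  homologs in the outgroup background and in the depth-ordering tests.
* **Not emulated**: codon usage and selection, multi-exon structure
  (behind the adapter boundary), genome rearrangements, real annotation
  error modes beyond whole-gene dropout, and profile-width variation
  between families. A green test establishes that the pipeline's
  decisions are correct in a world with the stated statistical structure;
  it does not establish calibration of R or S on real proteomes.

# Determinism and numerical notes

Everything downstream of the inputs is deterministic: greedy orders are
fixed, ties break lexicographically, species are processed in sorted
order, and tables are written in sorted row order — two runs from the
same inputs are byte-identical (asserted). Gap costs are
`open + (L−1)·ext` for a length-L gap. The boundary at the occupancy
threshold is inclusive; the hit gate is inclusive; the R ≥ 0.65, ΔR >
0.01, identity > 90% and S > 0.25 comparisons are strict in the direction
stated. Scores are plain doubles; the only tolerance used anywhere is
1e-9 on R comparisons.

# Known limitations

* The ORF-stub rescue cannot recover multi-exon genes; with a spliced
  gene finder plugged in, novelty checking and adoption apply unchanged.
* A family whose reference-species entries are both absent from the
  ortholog tables is invisible to seeding; rescue cannot create a group.
* Supergroup detection is quadratic in the number of groups (fine for
  tens of thousands of groups with early exit, but the all-member rule
  means dense families dominate the cost).
* The raw-bit hit gate is a crude stand-in for E-values; with short
  profiles (< ~15 states) it passes weak matches more readily.
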