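---
title: "Methods: mining, topology and transfer inference for LuxI/LuxR cassettes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining, topology and transfer inference for LuxI/LuxR cassettes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`luxcassette` implements a desk-scale comparative-genomics survey of
LuxI/LuxR quorum-sensing machinery: domain-based candidate mining,
redundancy reduction, *luxI/luxR* cassette pairing and topology
classification, amino-acid-composition comparison, reference-anchored
conservation, and phylogenetic inference of horizontal gene transfer (HGT)
and cassette co-transfer. This vignette records the models behind each
stage, the tunable parameters and why their defaults are what they are,
what the synthetic-data generators do and do not emulate, and the design
decisions taken where the methodology was genuinely open.

## Candidate mining

LuxI synthases are recognised by the autoinducer-synthase domain
(IPR001690). LuxR-family regulators are recognised by a *two-domain*
requirement: a C-terminal DNA-binding signature (LuxR-type HTH IPR000792,
or the winged-HTH superfamily IPR011991) **and** an
autoinducer/ligand-binding-class domain. The two-domain rule is what
separates AHL-responsive regulators (including "LuxR solos", which have
both domains but no cognate synthase nearby) from the far larger crowd of
HTH transcription factors.

Annotation pipelines do not agree on a canonical list of
autoinducer-binding-class signatures, so the ABD set is an explicit,
auditable parameter (`mining_config()$luxr_abd_domains`). The default —
IPR005143 (LuxR-type autoinducer-binding domain), IPR029016 (GAF-like
ligand pocket), IPR011006 and IPR001789 (CheY-like receiver domains, the
signal-accepting modules of two-component systems) — is a reconstruction,
and `select_luxr()` refuses to run with an empty set rather than silently
degenerating to a one-domain filter.

Length windows: regulators are restricted to 200–300 residues, the
canonical envelope of LuxR-family proteins; synthases default to a
permissive 150–350 residues around the observed 191–292 range, since the
mining literature filters synthases by domain rather than length.

## Redundancy reduction

`greedy_cluster()` follows the classic CD-HIT scheme: sort by decreasing
length, let each sequence join the first cluster whose representative it
matches at or above the threshold (default 0.30), otherwise found a new
cluster. Identity is computed by full global Needleman–Wunsch alignment
(match +1, mismatch 0, linear gap −1) rather than a k-mer pre-filter:
inputs here are hundreds of sequences at most, and exact identity makes
the representative-set invariants (representatives mutually below
threshold; every member at or above threshold to its representative)
checkable. Two conventions needed fixing:

* **Denominator** — identity is matches / alignment length by default;
  matches / shorter-sequence-length is available via argument. The
  alignment-length convention is the more conservative of the two.
* **Traceback ties** — co-optimal alignments can disagree on match counts,
  so the traceback preference is fixed (diagonal, then gap-in-second, then
  gap-in-first), making identity a pure function of its inputs. The test
  suite checks the C++ implementation against an independent plain-R
  dynamic-programming oracle with the same convention.

## Cassette pairing and topology

Coordinates are 1-based inclusive throughout (the GFF3 convention). The
distance between a *luxI* and a *luxR* is the number of bases strictly
between the two ORFs (`right start − left end − 1`): the intervening-gene
semantics of the topology grammar only make sense for boundary-to-boundary
gaps. Pairing is a greedy matching by increasing gap (each *luxR* used at
most once; ties resolve to the leftmost pair), which makes the result
invariant to input order.

`max_gap_bp` defaults to **3400** rather than the stricter 3000 sometimes
used for canonical-cassette definitions: the widest annotated Gram-positive
pair sits at a 3258 bp gap, so only the 3400 criterion admits all six
reported cassettes; both criteria are exposed and the acceptance script
reports both counts.

Topology strings render each gene as an arrow over its strand in
left-to-right replicon order (`R>` forward regulator, `<I` reverse
synthase), with `X(n)` for n intervening genes and an `X(>7)` bucket above
seven — intervening genes are counted on both strands, since the notation
is strand-unqualified. `orf_length_aa()` assumes gene spans include the
stop codon (`span/3 − 1` residues) and rejects spans not divisible by
three; the bundled six-cassette coordinates are all consistent with that
convention, giving the two shortest synthases exactly 191 residues.

The bundled `grampos_cassette_features()` table carries the published
locus coordinates with strands taken from the annotated transcription
arrows; the intervening "X" genes inside the two `X(>7)` gaps and the
`X(2)` gap are synthetic filler (only their counts are annotated, not
their positions), and are flagged as such in the documentation.

## Composition comparison

Composition is per sequence: `Comp(x) = A_x / N` over the 20 standard
residues, with `X` excluded from numerator and denominator. Group
comparison reports the fold change of group-1 over group-2 means and a
two-sided p-value per residue; a residue is significant when FC ≤ 0.80 or
FC ≥ 1.20 **and** p < 0.05.

Three open choices and their resolutions:

* **The test** is unnamed in most survey write-ups; the default is Welch's
  *t* on per-sequence fractions (n ≥ 2 per group), with Mann–Whitney as the
  selectable rank alternative for small or skewed groups.
* **Per-sequence vs pooled** — per-sequence distributions are the default
  (each protein is one observation); a pooled-count fold change (weighted
  by sequence length) is available via `pooled_fc = TRUE`.
* **Multiple testing** — raw p-values by default, matching how such
  thresholds are conventionally applied; Benjamini–Hochberg is opt-in
  (`adjust = TRUE`).

A residue absent from the denominator group yields an infinite fold change
flagged via `fc_defined = FALSE`, never a silent drop.

## Conservation

`site_conservation()` anchors every alignment column to the ungapped
coordinate system of a reference sequence (e.g. *V. fischeri* LuxI
P12747) and reports, per reference position, the percentage of
non-reference rows matching the reference residue; gaps count as
mismatches. The conservation call threshold defaults to **50 %** — the
smallest level at which published invariant-residue lists retain their
weakest members — and exact percentages are kept alongside the rounded
integers used for reporting. The module consumes alignments; it does not
align (alignment construction is out of scope, any aligner's FASTA output
works).

## Phylogenetics

* **Distances** — p-distance over pairwise-comparable (both non-gap)
  columns, with the Poisson multiple-hit correction `−ln(1 − p)` as
  default for tree building; saturated pairs are flagged infinite rather
  than clamped.
* **Neighbor joining** — standard Saitou–Nei agglomeration, implemented in
  the package so the tie-break is documented and deterministic: among
  Q-minimising pairs, the lexicographically smallest (representative tip
  label) pair wins. Negative branch lengths are clamped to zero and
  counted. On exactly additive matrices NJ provably recovers the
  generating topology; the tests assert RF = 0 against 50 random 6–10-taxon
  trees and cross-check against the reference implementation in `ape`.
* **Bootstrap** — column resampling with replacement; support = percentage
  of replicate trees containing the same bipartition; seeded and
  reproducible bit-for-bit. 1000 pseudo-replicates is the
  publication-grade default; the simulation studies in the tests use 100
  to keep runtimes proportionate.
* **Robinson–Foulds** — count of non-trivial bipartitions unique to one
  tree, from the same canonical bipartition keys used for bootstrap
  counting; the oracle in the tests is an exhaustive bipartition-set
  comparison plus `phangorn::RF.dist`.

## HGT detection

A transfer call needs three ingredients, mirroring how such events are
argued in comparative surveys: a gene-tree clade mixing gram-positive and
gram-negative tips; high bootstrap support for that clade; and
contradiction of the 16S rRNA reference topology. `detect_hgt()` scans
every internal edge, examines the smaller bipartition side, and emits a
call for each gram-mixed side with verdicts:

* `hgt_supported` — support ≥ `min_support` (default **70**; "high
  support" is conventionally 70+, and values just below have been treated
  as supporting in the survey literature) **and** reference-incongruent;
* `candidate` — supported but not contradicting the reference;
* `rejected` — support below the cutoff.

Reference incongruence is a bipartition test restricted to shared tips:
the reference must itself separate the gram labels (contain the
gram-positive/gram-negative bipartition), in which case a gram-mixed gene
clade that is not a reference clade contradicts label monophyly. This is a
deliberate formalization of a qualitative criterion ("clustered separately
in the 16S tree"); full gene-tree/species-tree reconciliation is out of
scope. Shared ecological niche between cross-gram members is annotated
(`niche_match`) as corroborating evidence but not required — niche data is
descriptive, not diagnostic.

## Cassette co-transfer

For each cassette, `classify_transfer_mode()` finds the nearest
gram-negative partner (patristic distance; ties to the higher-support
ancestor, then alphabetically) of its LuxI, LuxR and concatenated
sequences in the three respective trees. Because an NJ tree's root
trifurcation is arbitrary, supports are read after re-rooting on the
farthest tip outside the partner pool (with supports kept bound to edges).
Verdicts are built from *supported claims only*:

* `simultaneous` — all three partners agree and each joining clade is
  supported: the cassette moved as one unit.
* `individual` — the LuxI and LuxR partners differ, the transferred gene's
  grouping is supported, and the other gene's tree contains a supported
  bipartition *separating* the cassette from that partner. The asymmetry
  is deliberate: a vertically inherited gene has no meaningful "partner"
  — its nearest gram-negative is whichever tip happens to flank the deep
  split, a grouping that never earns meaningful support — but its tree
  can still *exclude* the other gene's donor with full confidence, and
  that supported disagreement is what "transferred individually" means.
* `unclear` — everything else: missing tips, unsupported groupings,
  or a concatenated placement contradicting both gene placements.

Co-transfer classification is intended for cassettes with prior transfer
evidence (it is how one asks "did the pair move together?"); applied to
vertically inherited cassettes it can report `individual` spuriously,
since arbitrary nearest-partners across trees rarely coincide.

## Synthetic data: what it emulates, and what it does not

The generators produce every input the pipeline consumes, with planted
ground truth serialized alongside:

* `make_replicons()` — one replicon per requested cassette topology
  (pattern grammar in, GFF3 out), with gene lengths drawn from the
  observed envelopes (synthases 191–292 aa, regulators 200–300 aa,
  stop-codon-inclusive spans), intervening filler genes packed into the
  requested gap, and decoy solo pairs placed beyond the distance
  criterion. Default cassette specs are the four observed topology classes
  at their annotated gaps (222, 162, 730 and 883 bp).
* `make_aac_groups()` — i.i.d. sequences from SwissProt-wide average
  residue frequencies (group 1) and from the same frequencies with planted
  multipliers, renormalised (group 2); lengths uniform over 200–300
  residues, 50 sequences per group. Note a planted 1.4× multiplier on one
  residue implies an expected fold change of ≈ 1.35 after renormalisation.
* `evolve_on_tree()` — a two-clade species tree (8 + 8 tips by default)
  with gram labels monophyletic by construction, within-clade branch
  lengths uniform on 0.06–0.2 expected substitutions/site (bounded away
  from zero so every split is resolvable at the simulated alignment
  lengths) and a 0.5 stem per clade side; sequences evolve under an
  equal-rates (Poisson-style) amino-acid process via `phangorn::simSeq`,
  200 columns per gene by default. Transfers are planted by detaching the
  recipient and re-attaching it near the end of the donor's terminal
  branch (attachment branch 0.02), which guarantees the gene-tree signal a
  real transfer leaves; `donor = "auto"` picks the deepest gram-negative
  tip, a donor whose transfer signal cannot be confused with vertical
  proximity. Recipient and donor share a niche label.

What the generators do **not** emulate: indel evolution (alignments are
gap-free by construction, though all consumers handle gaps),
site-rate heterogeneity and realistic substitution matrices (an LG hook
would slot into the simulator, but the detection logic under test is
model-agnostic), genome composition (GC content, codon usage, operon
structure), and annotation noise (every gene is correctly classified).
Passing tests therefore demonstrate that the *logic* of each stage is
correct under its stated model, not that the pipeline is robust to
real-world annotation error or alignment uncertainty.

## Problem sizes and numerical choices

The simulation studies in the test suite and acceptance script use: 20
seeded composition comparisons at n = 50 per group (planted and null), 50
random 6–10-taxon trees for NJ exactness, 20 planted-transfer simulations
with matched no-event controls (16-tip trees, 200-column alignments, 100
bootstrap replicates), and 10 co-transfer scenarios (alternating joint and
single-gene events). These sizes give stable pass/fail behaviour for the
stochastic properties while keeping a full run in tens of seconds.

Numerical details: symmetric-matrix validation tolerates 1e-8 asymmetry;
Q-criterion ties use a relative 1e-12 band; Welch's test on zero-variance
groups returns p = 1 for equal means and p = 0 otherwise (perfectly
separated constants); bootstrap supports are reported as rounded
percentages; all seeded randomness goes through `withr::with_seed` so
callers' RNG state is never disturbed.

## Optional accession-based validation (network required)

The six cassette proteins carry their UniProt accessions in
`grampos_cassette_features()$protein_id`. With network access one can
fetch the Gram-positive LuxI set plus the *V. fischeri* references
(P12747, P12746), confirm the length envelope (mean ≈ 219 aa, minimum 191,
maximum 292 for the synthases), align them with any standard aligner, and
run `site_conservation()` against P12747 — strongly conserved synthase
positions such as R25 appear at 100 % identity. This validation depends on
external services and is therefore documented here rather than run in the
test suite.

## Known limitations

* Tree building is distance-based NJ; maximum-likelihood trees (e.g.
  LG+G+I) are not built in-package but import cleanly through
  `read_support_tree()`, and every downstream analysis is tree-agnostic.
* Exact membership of a CD-HIT-reduced representative set is not
  bit-reproducible across implementations (word size and denominator
  conventions differ); the package documents its own conventions instead.
* The reference-incongruence test requires the reference tree to separate
  the gram labels; with a non-monophyletic reference every mixed clade is
  reported as congruent (`candidate` at best), which is conservative.
* `detect_hgt()` calls name mixed *clades*, not donor/recipient roles;
  direction of transfer is not inferred.
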