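---
title: "Peptide-based clustering and annotation of protein families: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peptide-based clustering and annotation of protein families: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cupp)
library(data.table)
```

This vignette documents the model behind `cupp`, the tunable
parameters and their defaults, the numerical and design choices made
where the procedure is genuinely open, what the synthetic-data
generator does and does not emulate, and the known limitations.

## The model

### Peptide pools

A protein sequence is decomposed by a sliding window of length
`N = 8`; each clean window (standard residues only) contributes every
variant obtained by replacing exactly `A = 2` positions with the
wildcard `X` — `choose(8, 2) = 28` strings per window. The pool of a
protein is the set of (variant, 0-based window start) pairs. Because a
variant string encodes "these 6 residues at these positions", two
windows share a variant *iff* their Hamming distance is at most 2, so
all downstream matching is exact string equality over pools — no
alignment, no scoring matrices.

Choices made here:

* **Wildcard collision.** `X` doubles as the unknown-residue code in
  real data. We reserve `X` for the wildcard and treat any nonstandard
  input character (`X`, `B`, `Z`, `J`, `U`, `O`, `*`, gaps) as
  invalidating only the windows that contain it. A query or training
  protein with a stretch of unknowns loses those windows and nothing
  else.
* **Coordinates** are 0-based half-open `[start, start + N)`
  throughout, including the domain-range TSV and annotation output.
* `expand_variants()` refuses windows containing the wildcard, so
  pools can never be polluted by data-borne `X`.

### Within-family dissimilarity

For two proteins with pruned pools, shared peptides are found by
string equality; `shared_positions` is the count of distinct start
positions of shared peptides in the first protein plus the same count
in the second, `max_positions` the larger of the two proteins' overall
distinct start counts, and

$$ s_{ij} = \left(1 - \frac{\mathrm{shared\_positions}}
  {2\,\mathrm{max\_positions}}\right)^{c_\mathrm{clust}} $$

Identical pools give 0, peptide-disjoint pools give 1, and the
exponent `c_clust` (default 9, positive integer) sharpens contrast:
raising it never increases any score, and larger values produce fewer,
tighter groups. An empty pool is defined as maximally dissimilar
(score 1) to everything rather than an error, since empty pools arise
legitimately after aggressive pruning.

### Incremental clustering

One round consists of: prune peptides found in a single protein
(presence, not multiplicity, decides); remove outlier proteins whose
surviving peptides cover `< 20` residue positions or `< 10%` of the
family median coverage (both rules apply; removals are united); build
the dissimilarity matrix; Ward-link and cut at height 1; drop groups
below the round's minimum size; extract each group's conserved
peptides at the round's conservation floor; and merge sister groups by
complete linkage on a group-level dissimilarity, cut at 0.7. Rounds
tighten the floor 10 → 20 → 30 → 40% and the minimum size 2 → 3 → 4 →
5, each round keeping only the previous round's conserved peptides. A
final pass clusters on the 40%-conserved peptides and applies the
final minimum group size (default 5).

Open points decided here, visible as `clustering_params()` defaults:

* **Group-level dissimilarity.** "Shared conservation" between two
  groups is ambiguous (whose conservation to sum). We use, over
  peptides present in both groups, the mean of the two conservations,
  divided by the larger of the two groups' total conservation mass —
  the only reading that yields exactly 0 for identical groups and 1
  for peptide-disjoint ones, keeping the complete-linkage cut at 0.7
  meaningful on a [0, 1] scale.
* **Ward variant.** `stats::hclust(method = "ward.D2")` on the raw
  score matrix — the standard Ward agglomeration on a precomputed
  distance matrix, which the tests cross-check against an independent
  Lance–Williams implementation; the cut
  at height 1 is applied to raw merge heights, not normalized ones.
* **Final pass.** The last clustering round reuses the full round
  machinery (pruning, outlier removal, sister-group merge) on the
  40% peptides, with conservation extraction floor 0 — finalization
  applies the real retention cut. Whether the sister merge belongs in
  the final pass is not specified anywhere; including it keeps all
  five passes uniform.
* **Round minimum vs final minimum.** The per-round minimum group
  size is capped at `final_min_group_size`, so reduced settings
  (`reduced = TRUE`, final minimum 3, intended for sparse families)
  do not lose 3- and 4-member groups in the tightening rounds.
* **Determinism.** Proteins are processed in lexicographic id order,
  flat-cluster labels are renumbered by each group's smallest member
  id, and group labels `FAM:k` are assigned in that order. Reruns on
  identical input are byte-identical, which the tests assert on
  serialized libraries and annotation tables.
* **"Ignored" proteins.** Members of groups below a round's minimum
  size are removed from subsequent rounds and reported in
  `outliers` with a per-round reason, so
  groups ∪ outliers = input ids always holds.

### Finalization and the library

Peptides conserved in **strictly more than** 20% of a group's members
are retained and their conservation squared
(`conservation_weight()`): 0.9 → 0.81, 0.25 → 0.0625. The boundary
case 0.2 is *dropped* — the squaring transform itself maps it to
0.04, but it never enters a finalized group. Squaring preserves
within-group ranking while favoring strongly conserved peptides.
Each group records its members' metadata evidence (subfamily, EC,
taxonomy counts) and the mean number of residue positions its
retained peptides cover per member, which later parameterizes range
inference.

Compilation merges any number of families: a peptide occurring in
groups of `k` distinct families (families, not groups) has every
weight divided by `k`; peptides whose non-wildcard residues all lie
in `{G, A, V, L, I, P}` are banned (the aliphatic set plus proline is
our fixing of "abundant aliphatic amino acids or proline"; ignoring
wildcard positions is the most conservative reading, banning a
variant whenever its visible residues are all aliphatic). Each
group's *theoretical maximum* — the reference for all prediction-time
fractions — is recomputed from the adjusted weights, so filtering
stays consistent with lookup weights; computing it pre-adjustment
would make cross-family peptides count more in the denominator than
they ever could in a score.

The library serializes to a self-describing JSON archive (format
name, version, windowing parameters). Doubles are written as
`"%.17g"` strings because 17 significant digits are what IEEE-754
round-tripping requires; a reload is bit-exact.

### Prediction

Per query: window + expand, look every variant up in the index,
then per candidate group

1. `sum_unique`: summed weights with each peptide counted once.
   Filters: `sum_unique ≥ 5` and `≥ 1%` of the group's theoretical
   maximum.
2. *Fast mode* stops here, additionally requiring matched peptides at
   ≥ 8 distinct query start positions, and emits the family-level
   `FAM.0.0` label only — by design a superset of full-mode family
   hits.
3. *Full mode* builds the accumulation profile: per residue, the sum
   of weights of covering peptide occurrences, repeats counted (so
   tandem repeats accumulate). A valid domain needs ≥ 20 positions
   above 0.2.
4. Overlap resolution processes profiles by decreasing fraction of
   theoretical maximum (ties by label); a later profile is kept only
   if ≥ 50% of its accumulation mass falls outside already-occupied
   positions. The mass criterion (not position counts) follows from
   the "50% of the sum of peptide conservation" wording.
5. Ranges: runs of covered positions, bridging gaps up to the group's
   average covered-position count clamped to [50, 200] residues
   (`≤` semantics at the boundary).
6. Assignment: at ≥ 5% of the theoretical maximum the group label
   `FAM.k` with subfamily (only when ≥ 3 members' evidence agrees)
   and EC (majority function first, minority functions appended with
   `-`, the separator for functions originating from distinct source
   proteins; `&` joins co-occurring functions of one protein and is
   kept intact inside tokens). Below 5%: `FAM.0.1` (in the family,
   in no current group). Two kept calls of one family whose spans
   overlap reciprocally by ≥ 50% collapse to `FAM.0.2`; the 50%
   reciprocal-span rule is our concretization of "the same range".

Duplicate peptide occurrences are deliberately counted differently in
steps 1–2 (once) and steps 3–5 (per occurrence); both behaviors are
pinned by unit tests.

## Evaluation framework

`score_annotations()` compares per-protein label sets (a multimodular
protein carries several): sensitivity `tp/(tp+fn)`, precision
`tp/(tp+fp)`, F-score their harmonic mean, with `NA` (not 0) on empty
denominators. At the EC level, composite strings are split into
atomic functions on `;`, `&`, `-`; when a `known_ec` set is supplied
(the training folds' functions), a truth function outside it that is
predicted as unknown counts as correct — without this, hold-out folds
containing a family's only carrier of a function would be penalized
for the only reasonable answer.

`make_folds()` treats similarity clusters as atoms, deals them
largest-first into the current fold until it holds ≥ 1/k of the
proteins, then opens the next fold. `holdout_run()` trains on the
remaining folds end to end and scores the held-out fold at all three
levels.

## The synthetic generator

`generate_family()` draws per-group ancestors i.i.d. over the 20
standard residues (redrawn while any pair exceeds the allowed
between-group identity, default 0.5 — random ancestors sit near
0.05, so redraws are rare) and derives members by i.i.d. point
substitutions at the within-group rate. Substitutions always change
the residue, so expected member-to-ancestor identity is exactly
`1 − rate`. Metadata (subfamily, EC, taxonomy, fragment flags) is
assigned per group; 70%-identity single-linkage clusters are computed
as fold atoms; everything is reproducible from the seed without
touching the caller's RNG stream.

Default conditions — 5 groups × 12 members, 300 residues, 3%
within-group mutation, ancestors ≤ 50% identical — are the study
conditions used by the acceptance suite; they represent a
well-separated mid-sized family in which group structure is real but
members are not trivially identical.

What the generator does **not** emulate, and what passing tests
therefore cannot show: indels and alignment shifts (real families
have them; peptide windows tolerate substitutions, not frame shifts),
non-star within-group phylogeny, compositional bias (real linkers are
the reason for the aliphatic ban; synthetic sequences are uniform),
shared domains between families, and realistic family-size and
divergence distributions. Results on synthetic families bound the
method's behavior under its own assumptions; they do not certify
performance on curated databases.

One consequence of star-shaped groups deserves emphasis: at small
within-group rates every group is a single 70%-identity cluster, so a
cluster-aware hold-out with those atoms would remove whole groups
from training and measure novel-group rejection instead of
new-member generalization. The hold-out scenario in the tests
(rate 0.05) therefore splits on the generator's only finer
within-group structure — singleton atoms via
`make_folds(cluster_map = NULL)` — mirroring the scenario the
hold-out emulates, in which every held-out cluster has sibling
clusters of its group in training. For the same reason the synthetic
`.clstr` output is meant as fold atoms, not as a representative map:
collapsing each 70% cluster to one representative would reduce every
group to a single sequence.

## Problem sizes and numerical notes

The test and acceptance suites run families of 15–60 proteins of
120–300 residues — sizes chosen so the full five-pass clustering,
library compilation and prediction cycle completes in seconds to tens
of seconds per family while exercising every code path; clustering
cost is dominated by the all-pairs peptide joins, which scale with
shared-peptide mass rather than sequence length alone. Dissimilarity
ties are broken by lexicographic id, the oracle comparison for the
pairwise score is asserted to 1e-12, and flat cuts use `<=` at
thresholds (cut heights 1 and 0.7, gap bridging, 50% overlap, the
20-position floors) exactly as stated above, with boundary fixtures
in the tests.

## Known limitations

* Families above roughly 30,000 representatives should be pre-divided;
  the all-pairs distance matrix dominates memory and time.
* A diverse small branch can fall below the outlier/coverage floors
  and vanish from the model; reduced settings
  (`clustering_params(reduced = TRUE)`) recover smaller groups at the
  cost of specificity.
* Metadata stays protein-global: a multidomain training protein
  contributes its subfamily/EC evidence to every group any of its
  domains joins.
* EC assignment is evidence counting over group members, not
  catalytic-site modeling; minority functions are reported, not
  arbitrated.
* Fast mode trades the domain-length and overlap filters for speed
  and may admit false positives on repetitive or compositionally
  biased queries.
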