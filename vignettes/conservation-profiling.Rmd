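---
title: "Clade-partitioned conservation profiling: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clade-partitioned conservation profiling: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cladecons)
```

## The problem

Plant EuPEBP proteins — the FT/TFL1/MFT florigen family — are short
(~175-residue), highly conserved proteins whose members nevertheless carry
small sets of diagnostic residues that separate floral activators (FT-like)
from repressors (TFL1/CEN/BFT-like) and from the ancestral MFT-like forms.
Questions about this family are typically asked at the level of *clades*:
given a curated multiple sequence alignment and an assignment of every
sequence to a gene clade (AnFT, AnTCB, NaMFT, the monocot FT1…FTY clades,
…), which residues are conserved within each clade, which are unique to a
clade, how far have expanded clades diverged from a reference consensus,
and how did the clade complement itself evolve across lineages?

`cladecons` implements that workflow as composable, tested pieces:
character-set handling on reference numbering, per-clade consensus
profiling with banded conservation tiers, clade-unique signature detection,
divergence matrices, percent identity, and Dollo-parsimony reconstruction
of clade complements on a taxonomy. Clade definitions are always *inputs*
(labels in a partition table); no tree inference is performed here.

## Consensus tiers

For a clade with $n$ member sequences, each retained column is summarized
by the count of each amino acid, the gap count, and the count of `X`
symbols (ambiguous or untranslatable codons), which carry no amino-acid
identity and are excluded from both the counts and the gap tally. Let $f$
be the largest amino-acid fraction in the column. The call is banded with
strictly-greater-than semantics:

| band | condition |
|---|---|
| absent (`#`) | gap fraction > 0.5 |
| no consensus (`-`) | $f \le 0.30$, or a tie for the top count |
| weak consensus | $0.30 < f \le 0.50$ |
| consensus | $0.50 < f \le 0.75$ |
| conserved | $0.75 < f \le 0.90$ |
| highly conserved | $0.90 < f \le 0.95$ |
| very highly conserved | $0.95 < f \le 0.99$ |
| invariant | $f > 0.99$ |

All bounds are `tier_thresholds()` parameters and can be moved, but their
strict ordering is enforced. Note that "invariant" is $f > 0.99$, not
$f = 1$: with a few hundred sequences this tolerates a handful of
discordant sequences, which is the appropriate reading of a >99% band; a
user wanting strict invariance can set `invariant = 1 - 1e-12`.

Two deliberate tie-breaks:

* **Ties at the top count are called no consensus.** A consensus names *a
  single* amino acid; when two letters tie, none can be named. The tie is
  logged at WARNING level.
* **Denominator.** The default denominator for $f$ is *all member
  sequences* (gaps included), because "proportion of sequences with the
  amino acid" is the natural population statement. A `non_gap` mode is
  provided for profiles of fragmentary data where gaps are missing data
  rather than true deletions; it divides by the count of unambiguous
  residues instead. The absence call always uses the all-sequences gap
  fraction, regardless of mode.

The `absent` threshold (gap fraction > 0.5) is a package convention;
"absence" of a residue from a clade is not usually given a numeric
definition in the literature, and majority-gapped is the weakest defensible
reading.

## Signature residues and divergence

`unique_residues()` makes uniqueness *relational*: a residue is in clade
$C$'s signature set when $C$'s call reaches `min_focal_tier` (default
consensus, >50%) and no other clade in the comparison has the same
consensus letter there. Because "not found in other groups" is ambiguous —
does a *weak* consensus elsewhere disqualify? — both readings ship:

* `not_consensus_elsewhere` (default): only another clade's ≥ consensus
  call disqualifies;
* `not_weak_elsewhere`: even a weak consensus elsewhere disqualifies, which
  provably yields a subset of the default.

The criterion in force is stamped into every output, and a pseudo-clade
`All` is never used as a comparator (it would contain the focal clade).

`divergence_matrix()` compares focal clades (typically the expanded
monocot/grass FT clades) to a reference consensus (typically `EuFT`,
angiosperm FT without the monocots). Its tier scale is the full scale
*collapsed* to three bands (>90 / >75 / >50), not a second threshold
system. Residues at which every focal clade matches the reference are
omitted from the grid; the omission rule cannot hide a divergent cell,
which is asserted as a property test. The default residue selection —
reference-unique residues plus motif residues — is user-extensible because
informative positions (e.g. changes just outside a motif window) routinely
fall outside any fixed list.

Motif coordinates ship in two named profiles, `fig` (14-3-3a/b 60–64 and
95–101, P-loop 128–140, LYN 150–152) and `text` (59–65, 93–100, 127–140,
149–151), because both numbering conventions are used in the FT
structure–function literature; the profile is part of the configuration
and recorded in the manifest.

## Percent identity

`pairwise_identity()` has three explicit gap modes because desktop tools
disagree silently about gap handling: `exclude_any_gap` (default; identity
over columns where both sequences carry an unambiguous residue),
`gap_mismatch` (at least one residue in the column), and `gap_gap_match`
(shared gaps count as matches). `X` is treated as missing data in every
mode. Group means are arithmetic means of pairwise values — within-group
over unordered pairs, cross-group over the full Cartesian product — and
reported values are rounded to one decimal place only at write time.

## Dollo reconstruction

A clade's history is modelled as a single gain followed by any number of
losses. Given a taxonomy (Newick, internal labels honoured) and a presence
matrix (presence = count > 0), the gain is placed on the branch above the
MRCA of all possessing tips, and one loss is placed on each maximal
subtree containing no possessing tip. Under the single-gain constraint
this placement attains the minimum number of losses and is unique, so the
"fewer, deeper losses" preference is satisfied without any tie-breaking;
the test suite nevertheless verifies minimality against an exhaustive
enumeration of all internal-state assignments on random 8-tip trees.

Absence in a lineage known only from thin transcriptome sampling is weak
evidence of loss. Such taxa can be flagged `unreliable_absence`: they are
excluded from loss inference (their state is left free), a subtree whose
only non-possessing tips are unreliable incurs no loss, and the resulting
presences are flagged `inferred_only` — the analogue of drawing a
translucent circle rather than a solid one.

## The synthetic-data generator

`simulate_alignment()` plants, per clade and column, a consensus symbol at
a target top fraction: `round(f * n)` sequences receive the symbol (so the
target is realized to within $1/n$) and the remainder draw uniformly from
the 19 other amino acids — the most adversarial background for consensus
calling, since it maximizes the chance of a competing letter. Gaps are
placed independently per column at a configurable fraction. The recorded
truth is the tier implied by the *realized* counts, by direct band
arithmetic that does not route through the profiling code. The generator
emulates exactly the statistical structure the profiling stages assume —
exchangeable sequences within a clade, independent columns — and none of
the features of real alignments that they ignore (phylogenetic
autocorrelation within clades, indel structure, alignment error). Passing
recovery tests therefore validates the *machinery*, not the biological
fidelity of any particular dataset.

`simulate_history()` plants a gain node and disjoint loss subtrees on a
taxonomy and emits the resulting presence matrix with per-tip counts
`1 + Poisson(lambda)`; reconstruction recovers the planted loss count
whenever the planted history is the unique minimum, which the enumeration
oracle checks instance by instance.

Problem sizes used by the shipped validation suites: tier-band exactness
on 1000-sequence columns at every boundary; recovery on 3 clades × 300
sequences × 172 columns with planted fractions at least 0.02 from every
band boundary; Dollo minimality on 200 random 8-tip instances (the
enumeration oracle is exponential in internal nodes, so 8 tips keeps it
exact and fast). These sizes make the whole suite run in seconds while
leaving each property statistically meaningful.

## Numerical and interface choices

* Character-set columns are **1-based** (R convention) and strictly
  increasing; residue labels are 1-based positions in a chosen reference
  sequence (`label_by_reference()`), conventionally Arabidopsis FT, so
  outputs read as familiar residue numbers (Y85, Y134, W138, …).
* A curated character set loaded from TSV is authoritative over anything
  derivable by arithmetic: published core sets are hand-trimmed, and e.g.
  a 519-nucleotide alignment window does not necessarily correspond to
  its naive 173-codon translation once manually refined to a 172-residue
  protein set. `derive_character_set()` (occupancy ≥ 0.8 by default) is
  for de novo work only.
* Codon translation maps `---` to `-`, any partial-gap or `N` codon to
  `X` (logged), and stop codons to `X` with a warning; fragmentary
  transcriptome-derived sequences make all three common.
* Band comparisons are plain floating-point `>` against the threshold
  values; counts over common denominators (e.g. 300/1000 vs 0.30) round
  identically on both sides, so boundary behaviour is exact, and the test
  suite pins it at every boundary.
* Tier fractions at exactly a band boundary are assigned to the lower
  band ("strictly greater" semantics) — the reading under which a >99%
  band excludes 99.0% exactly.

## Limitations

* Conservation is frequency-based; no substitution-matrix weighting,
  sequence weighting for redundancy, or information-theoretic scores.
  Heavily over-sampled subclades therefore pull the consensus.
* Percent identity is raw identity, not an evolutionary distance; no
  Poisson or matrix correction.
* Dollo reconstruction treats the taxonomy as known and presence as
  binary evidence; it is not a probabilistic gene-tree/species-tree
  reconciliation and cannot date duplications.
* The generator's independence assumptions (columns, sequences) mean
  recovery results bound algorithmic correctness, not robustness to
  alignment error or phylogenetic correlation.
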