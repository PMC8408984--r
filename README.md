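# cladecons

Clade-partitioned conservation profiling and gene-family complement
reconstruction for plant protein families.

## What it is for

Gene families such as the plant EuPEBP (FT/TFL1/MFT "florigen") family are
studied as sets of *clades*: curated groups of sequences (AnFT, AnTCB,
NaMFT, the monocot FT1…FTY clades, …) defined by prior phylogenetic work.
`cladecons` takes a gapped alignment, a sequence → clade/taxon partition
table, a character set on reference residue numbering, and a taxonomy
tree, and computes the bespoke analytics this kind of study needs:

* **Consensus tiers.** For each clade and each retained residue, the top
  amino-acid fraction *f* is banded: weak consensus (*f* > 30%), consensus
  (>50%), conserved (>75%), highly conserved (>90%), very highly conserved
  (>95%), invariant (>99%); `-` when no letter exceeds 30% (or the top
  count is tied), `#` when the residue is majority-gap. Tier censuses
  summarize each clade row.
* **Clade-unique signature residues**: residues where a clade holds a
  consensus letter that no other compared clade shares (two uniqueness
  criteria, stamped into the output), with functional-motif annotation
  (14-3-3 interaction surface, P-loop, LYN triad) on Arabidopsis FT
  numbering.
* **Divergence matrices** of focal clades against a reference consensus
  (e.g. grass FT clades vs eudicot FT), on a collapsed >90/>75/>50 scale,
  omitting residues where nothing differs; per-motif integrity reports
  flag fully decayed motifs.
* **Percent identity** over the character set, with three explicit gap
  modes, pairwise, matrix-wide and as group means.
* **Dollo parsimony**: from a taxa × clade presence matrix, each clade is
  gained once on the branch above the MRCA of its possessing lineages and
  lost on the minimal set of branches; unreliable absences (thin
  transcriptome sampling) can be excluded from loss inference.
* **A seeded synthetic-data generator** that plants known tiers, unique
  residues and gain/loss histories, so every stage is validated against
  ground truth without any download.

Codon alignments are supported natively (`translate_alignment()` maps
`---` to `-`, partial-gap/`N` codons to `X`), matching the common practice
of storing curated family alignments at the nucleotide level.

## Worked example

Using the synthetic demonstration alignment shipped with the package
(4 clades × 8 sequences × 40 columns, generated by
`simulate_alignment()`), plus the curated streptophyte lineage counts:

```r
library(cladecons)
aln  <- read_fasta_alignment(system.file("extdata", "synthetic_eupebp_alignment.fasta",
                                         package = "cladecons"), "aa")
part <- read_partition(system.file("extdata", "synthetic_eupebp_partition.tsv",
                                   package = "cladecons"))
tab  <- consensus_table(aln, character_set(1:40), part,
                        c("EuFT", "FT1", "FT10", "AnTCB"))
tab
#> consensus table: 4 clade(s) x 40 residues (denominator: all)
#>   EuFT     TFALEVTRHEFQYVRDKEFPFYCIDKKKKKKEVPFECVDT
#>   FT1      TFALEVTRHEFQYVRDKEFPFYCIDEEEEEREVPFECVDT
#>   FT10     TFALEVTRHEFQYVRDKEFPFYCIDALMRIE-----CVDT
#>   AnTCB    TFALEVTRHEFQYVRDKEFPFYCIDALMRIEEVPFE####
```

The rows read like the consensus lanes of a family conservation figure:
all four clades agree over the conserved core, `FT10` has lost consensus
over a five-residue window (`-----`), and `AnTCB` is gapped out (`####`)
at the C-terminal columns. Censusing the FT10 row counts those calls:

```r
tier_census(tab$FT10)
#>  absent  no_consensus  ...  conserved  ...  invariant  conserved_plus
#>       0             5  ...         35  ...          0              35
```

Signature detection recovers the six residues where `EuFT` holds a private
consensus letter (here a planted `K` run at labels 26–31):

```r
unique_residues(tab, "EuFT")
#>   clade residue_label symbol      tier
#> 1  EuFT            26      K conserved
#> ...
#> 6  EuFT            31      K conserved
```

Reconstructing the EuPEBP clade complement across streptophyte lineages
from the curated count table, treating the Charales absence as missing
data:

```r
pm   <- read_presence_matrix(system.file("extdata", "eupebp_clade_counts.tsv",
                                         package = "cladecons"))
tree <- ape::read.tree(system.file("extdata", "streptophyte_lineages.nwk",
                                   package = "cladecons"))
rec  <- dollo_reconstruct(tree, pm, unreliable_absence = "Charales")
rec
#> Dollo reconstruction: 11 clade gain(s), 2 loss(es)
subset(rec$events, event == "loss")
#>   clade         parent       child event
#> 2 prMFT           zcc1 land_plants  loss
#> 4   MFT euphyllophytes seed_plants  loss
```

Each of the 11 observed clades is gained exactly once; the algal
proto-MFT label is lost where land-plant MFT takes over, and the generic
MFT label is lost at seed plants, where the matrix records the named
MFTA/MFTB and MFT1/MFT2 clades instead. `complement_timeline(rec,
"seed_plants")` returns the inferred complement at any named ancestor.

The full pipeline (`run_pipeline()`, or `inst/cli/cladecons.R` from a
shell) chains profile → census → signatures → divergence → identity →
complement, writing TSV outputs, a JSON manifest and a log into a run
directory; identical configurations give identical outputs.

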