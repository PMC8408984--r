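Package: cladecons
Title: Clade-Partitioned Conservation Profiling and Gene-Family Complement
    Reconstruction for Plant Protein Families
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the molecular evolution of plant protein
    families such as the EuPEBP (FT/TFL1/MFT) florigen family. Reads codon
    and amino-acid multiple sequence alignments, derives and applies trimmed
    character sets with reference-based residue numbering, computes per-clade
    per-residue consensus profiles classified into banded conservation tiers,
    detects clade-unique signature residues and motif decay, builds divergence
    matrices of focal clades against a reference consensus, computes percent
    identity over a character set, and reconstructs gene-clade gain/loss
    histories on a taxonomy by Dollo parsimony. A seeded synthetic-data
    generator plants known conservation structure and gain/loss histories so
    every stage can be validated against ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
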