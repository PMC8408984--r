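random_calls <- function(labels) {
  n <- length(labels)
  tiers <- sample(tier_levels, n, replace = TRUE)
  symbols <- vapply(tiers, function(t) {
    if (t == "absent") "#"
    else if (t == "no_consensus") "-"
    else sample(cladecons:::AA_LETTERS, 1)
  }, character(1))
  mk_calls(labels, symbols, tiers)
}

test_that("unique residues require focal conservation and exclusivity", {
  tab <- make_table(list(
    A = mk_calls(10:12, c("K", "G", "E"),
                 c("invariant", "consensus", "weak_consensus")),
    B = mk_calls(10:12, c("E", "G", "E"),
                 c("consensus", "consensus", "consensus")),
    C = mk_calls(10:12, c("E", "G", "K"),
                 c("consensus", "invariant", "conserved"))))
  sig <- unique_residues(tab, "A")
  # label 10: A fixes K, others E -> unique; label 11: shared G -> excluded;
  # label 12: focal only weak -> below min_focal_tier
  expect_equal(sig$residue_label, 10L)
  expect_equal(sig$symbol, "K")
  for (cl in c("B", "C")) {
    expect_false(11L %in% unique_residues(tab, cl)$residue_label)
  }
  expect_error(unique_residues(tab, "Z"), class = "cladecons_partition_error")
})

test_that("uniqueness is relational: a new clade sharing the symbol removes the label", {
  base <- list(
    A = mk_calls(1:2, c("K", "R"), c("invariant", "invariant")),
    B = mk_calls(1:2, c("E", "E"), c("consensus", "consensus")))
  expect_setequal(unique_residues(make_table(base), "A")$residue_label, 1:2)
  base$C <- mk_calls(1:2, c("K", "D"), c("consensus", "consensus"))
  expect_equal(unique_residues(make_table(base), "A")$residue_label, 2L)
})

test_that("the strict criterion yields a subset and both match a brute-force scan", {
  set.seed(52)
  for (rep in 1:20) {
    labels <- 1:12
    tab <- make_table(list(A = random_calls(labels), B = random_calls(labels),
                           C = random_calls(labels), D = random_calls(labels)))
    for (cl in names(tab)) {
      loose <- unique_residues(tab, cl, criterion = "not_consensus_elsewhere")
      strict <- unique_residues(tab, cl, criterion = "not_weak_elsewhere")
      expect_true(all(strict$residue_label %in% loose$residue_label))
      expect_equal(loose$residue_label,
                   oracle_unique(tab, cl, criterion = "not_consensus_elsewhere"))
      expect_equal(strict$residue_label,
                   oracle_unique(tab, cl, criterion = "not_weak_elsewhere"))
    }
  }
})

test_that("motif annotation tags ranges and key residues on reference numbering", {
  calls <- mk_calls(1:172, rep("G", 172), rep("consensus", 172))
  ann <- annotate_motifs(calls, motif_map("fig"))
  expect_equal(ann$motifs[ann$residue_label == 134], "p_loop")
  expect_true(ann$key_residue[ann$residue_label == 134])
  expect_equal(ann$motifs[ann$residue_label == 151], "lyn_triad")
  expect_equal(ann$motifs[ann$residue_label == 20], "")
  expect_false(ann$key_residue[ann$residue_label == 20])
  # alternative published coordinate profile shifts the LYN triad
  ann2 <- annotate_motifs(calls, motif_map("text"))
  expect_equal(ann2$motifs[ann2$residue_label == 149], "lyn_triad")
  short <- mk_calls(1:40, rep("G", 40), rep("consensus", 40))
  expect_error(annotate_motifs(short, motif_map()),
               class = "cladecons_config_error")
})

test_that("divergence cells report focal symbol, collapsed tier and reference match", {
  tab <- make_table(list(
    EuFT = mk_calls(59:63, c("D", "G", "L", "R", "T"),
                    rep("invariant", 5)),
    FT1 = mk_calls(59:63, c("P", "G", "M", "R", "T"),
                   c("conserved", "invariant", "highly_conserved",
                     "invariant", "invariant")),
    FTY = mk_calls(59:63, c("D", "G", "L", "R", "V"),
                   c("invariant", "invariant", "consensus", "invariant",
                     "conserved"))))
  div <- divergence_matrix(tab, c("FT1", "FTY"), "EuFT",
                           residue_selection = 59:63)
  # residues 60 and 62 match everywhere -> omitted
  expect_setequal(unique(div$residue_label), c(59L, 61L, 63L))
  ft1_61 <- div[div$clade == "FT1" & div$residue_label == 61, ]
  expect_equal(ft1_61$symbol, "M")
  expect_false(ft1_61$matches_reference)
  expect_equal(ft1_61$tier, "highly")
  fty_63 <- div[div$clade == "FTY" & div$residue_label == 63, ]
  expect_equal(fty_63$symbol, "V")
  expect_false(fty_63$matches_reference)
  expect_equal(fty_63$tier, "conserved")
  # FTY matches the reference at 59 but FT1 does not: cell kept for both
  expect_true(div[div$clade == "FTY" & div$residue_label == 59,
                  "matches_reference"])
  expect_error(divergence_matrix(tab, c("FT1", "EuFT"), "EuFT"),
               class = "cladecons_precondition_error")
})

test_that("a focal clade identical to the reference leaves an empty grid", {
  calls <- mk_calls(1:6, c("G", "K", "L", "V", "R", "D"),
                    rep("invariant", 6))
  tab <- make_table(list(EuFT = calls, FT1 = calls))
  div <- divergence_matrix(tab, "FT1", "EuFT", residue_selection = 1:6)
  expect_equal(nrow(div), 0L)
  expect_setequal(attr(div, "omitted"), 1:6)
})

test_that("omission never hides a residue at which some focal clade diverges", {
  set.seed(53)
  for (rep in 1:15) {
    labels <- 1:10
    tab <- make_table(list(R = random_calls(labels), F1 = random_calls(labels),
                           F2 = random_calls(labels)))
    div <- divergence_matrix(tab, c("F1", "F2"), "R",
                             residue_selection = labels)
    for (lb in setdiff(labels, attr(div, "omitted"))) {
      cells <- div[div$residue_label == lb, ]
      expect_equal(nrow(cells), 2L)
    }
    for (lb in attr(div, "omitted")) {
      for (cl in c("F1", "F2")) {
        expect_equal(tab[[cl]]$symbol[lb], tab$R$symbol[lb])
      }
    }
  }
})

test_that("motif integrity flags decayed motifs and matches a manual recount", {
  labels <- 55:105
  ref <- mk_calls(labels, rep("G", length(labels)),
                  rep("invariant", length(labels)))
  decayed <- ref
  decayed$symbol[decayed$residue_label %in% 60:64] <- "-"
  decayed$tier[decayed$residue_label %in% 60:64] <-
    factor("no_consensus", levels = tier_levels, ordered = TRUE)
  motifs <- motif_map("fig")
  motifs$ranges <- motifs$ranges[c("fourteen33_a", "fourteen33_b")]
  rep_ <- motif_integrity_report(make_table(list(R = ref, Dk = decayed)),
                                 "Dk", "R", motifs)
  expect_true(rep_$decayed[rep_$motif == "fourteen33_a"])
  expect_false(rep_$decayed[rep_$motif == "fourteen33_b"])
  expect_equal(rep_$no_consensus[rep_$motif == "fourteen33_a"], 5L)
  expect_equal(rep_$match[rep_$motif == "fourteen33_b"], 7L)

  same <- motif_integrity_report(make_table(list(R = ref, S = ref)),
                                 "S", "R", motifs)
  expect_false(any(same$decayed))

  set.seed(54)
  for (rep in 1:8) {
    tabs <- make_table(list(R = random_calls(labels),
                            A = random_calls(labels),
                            B = random_calls(labels)))
    got <- motif_integrity_report(tabs, c("A", "B"), "R", motifs)
    for (i in seq_len(nrow(got))) {
      cl <- got$clade[i]
      rng <- motifs$ranges[[got$motif[i]]]
      idx <- which(tabs$R$residue_label %in% rng)
      states <- vapply(idx, function(k) {
        frow <- tabs[[cl]][k, ]; rrow <- tabs$R[k, ]
        if (as.character(frow$tier) == "absent") "absent"
        else if (match(as.character(frow$tier), tier_levels) <
                 match("consensus", tier_levels)) "no_consensus"
        else if (match(as.character(rrow$tier), tier_levels) >=
                 match("consensus", tier_levels) &&
                 frow$symbol == rrow$symbol) "match"
        else "mismatch"
      }, character(1))
      expect_equal(got$match[i], sum(states == "match"))
      expect_equal(got$mismatch[i], sum(states == "mismatch"))
      expect_equal(got$decayed[i],
                   length(states) > 0 &&
                     all(states %in% c("mismatch", "no_consensus")))
    }
  }
})
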