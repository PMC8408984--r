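test_that("column profiles count residues, gaps and ambiguity as specified", {
  aln <- aa_alignment(c(a = "GG", b = "GG", c = "G-", d = "GX"))
  cs <- character_set(1:2)
  pr <- profile_columns(aln, cs, c("a", "b", "c", "d"))
  expect_equal(pr[[1]]$counts, c(G = 4L))
  expect_equal(pr[[1]]$gap_count, 0L)
  expect_equal(pr[[2]]$counts, c(G = 2L))
  expect_equal(pr[[2]]$gap_count, 1L)
  expect_equal(pr[[2]]$x_count, 1L)
  expect_equal(pr[[2]]$n_sequences, 4L)
  expect_error(profile_columns(aln, cs, character(0)),
               class = "cladecons_precondition_error")
})

test_that("profile_columns matches a brute-force recount on random alignments", {
  set.seed(21)
  for (rep in 1:12) {
    aln <- random_alignment(sample(2:10, 1), sample(2:10, 1),
                            gap_prob = 0.15, x_prob = 0.05)
    cs <- character_set(sort(sample(alignment_length(aln),
                                    sample(alignment_length(aln), 1))))
    ids <- sample(alignment_ids(aln), sample(nrow(aln), 1))
    got <- profile_columns(aln, cs, ids)
    want <- oracle_profile(aln, cs, ids)
    for (k in seq_along(got)) {
      expect_equal(got[[k]]$counts[order(names(got[[k]]$counts))],
                   want[[k]]$counts)
      expect_equal(got[[k]]$gap_count, want[[k]]$gap_count)
      expect_equal(got[[k]]$x_count, want[[k]]$x_count)
      expect_equal(got[[k]]$n_sequences, want[[k]]$n_sequences)
    }
  }
})

test_that("tier bands use strictly-greater-than semantics at every boundary", {
  th <- tier_thresholds()
  # n = 100: at the boundary the call stays in the lower band; one more
  # sequence crosses it.
  cases <- list(
    list(at = 30L, below = "no_consensus", above = "weak_consensus"),
    list(at = 50L, below = "weak_consensus", above = "consensus"),
    list(at = 75L, below = "consensus", above = "conserved"),
    list(at = 90L, below = "conserved", above = "highly_conserved"),
    list(at = 95L, below = "highly_conserved", above = "very_highly_conserved"),
    list(at = 99L, below = "very_highly_conserved", above = "invariant"))
  for (cs in cases) {
    for (delta in 0:1) {
      k <- cs$at + delta
      counts <- c(G = k)
      rest <- 100L - k
      # spread the remainder thinly so no other letter competes
      filler <- rep(floor(rest / 19), 19)
      filler[seq_len(rest - sum(filler))] <- filler[seq_len(rest - sum(filler))] + 1L
      names(filler) <- setdiff(cladecons:::AA_LETTERS, "G")
      counts <- c(counts, filler[filler > 0])
      call <- classify_tier(mk_profile(counts), th)
      expect_equal(as.character(call$tier),
                   if (delta == 0) cs$below else cs$above,
                   label = sprintf("f = %d%% + %d", cs$at, delta))
    }
  }
})

test_that("consensus calls handle absence, no-consensus, ties and weak consensus", {
  th <- tier_thresholds()
  inv <- classify_tier(mk_profile(c(G = 100L)), th)
  expect_equal(inv$symbol, "G")
  expect_equal(as.character(inv$tier), "invariant")

  weak <- classify_tier(mk_profile(c(A = 40L, V = 35L, L = 25L)), th)
  expect_equal(weak$symbol, "A")
  expect_equal(as.character(weak$tier), "weak_consensus")

  abs_ <- classify_tier(mk_profile(integer(0), gap = 10L, n = 10L), th)
  expect_equal(abs_$symbol, "#")
  expect_equal(as.character(abs_$tier), "absent")

  nc <- classify_tier(mk_profile(c(L = 28L, A = 26L, V = 26L, G = 20L)), th)
  expect_equal(nc$symbol, "-")
  expect_equal(as.character(nc$tier), "no_consensus")

  tie <- classify_tier(mk_profile(c(A = 40L, V = 40L, L = 20L)), th)
  expect_equal(tie$symbol, "-")
  expect_equal(as.character(tie$tier), "no_consensus")
})

test_that("the non-gap denominator rescales the top fraction", {
  # 40 G of 100, but 60 gapped: over all sequences G is weak consensus;
  # over non-gap sequences it is invariant. Gap fraction 0.6 > 0.5 however
  # calls the residue absent first, so use gap 0.5 exactly.
  p <- mk_profile(c(G = 40L, A = 10L), gap = 50L, n = 100L)
  all_call <- classify_tier(p, denominator = "all")
  ng_call <- classify_tier(p, denominator = "non_gap")
  expect_equal(as.character(all_call$tier), "weak_consensus")
  expect_equal(as.character(ng_call$tier), "conserved")
  expect_equal(ng_call$top_fraction, 0.8)
})

test_that("classify_tier is monotone in the top fraction", {
  th <- tier_thresholds()
  lv <- tier_levels
  prev <- 0
  for (k in seq(1, 200)) {
    call <- classify_tier(mk_profile(c(G = k, A = max(0L, 200L - k))[
      c(G = k, A = max(0L, 200L - k)) > 0], n = 200L), th)
    cur <- match(as.character(call$tier), lv)
    if (k > 100) {   # G strictly dominant from here on: no ties
      expect_gte(cur, prev)
      prev <- cur
    }
  }
})

test_that("consensus tables align clades on shared labels and support 'All'", {
  aln <- aa_alignment(c(a1 = "GGK", a2 = "GGK", b1 = "GAK", b2 = "GAK"))
  part <- clade_partition(c("a1", "a2", "b1", "b2"),
                          c("A", "A", "B", "B"), rep("t", 4))
  cs <- character_set(1:3)
  tab <- consensus_table(aln, cs, part, c("A", "B", "All"))
  expect_equal(tab$A$symbol, c("G", "G", "K"))
  expect_equal(tab$B$symbol, c("G", "A", "K"))
  expect_equal(as.character(tab$A$tier), rep("invariant", 3))
  # disjoint fixed residues at column 2: each clade shows its own letter
  expect_equal(tab$All$symbol[2], "-")   # 50/50 tie across the union
  expect_equal(as.character(tab$All$tier)[1], "invariant")
  expect_error(consensus_table(aln, cs, part, c("A", "Z")),
               class = "cladecons_partition_error")
})

test_that("planted tiers are recovered on seeded synthetic alignments", {
  fractions <- c(0.2, 0.4, 0.65, 0.85, 0.93, 0.97, 1.0)
  set.seed(31)
  plan <- do.call(rbind, lapply(c("A", "B"), function(cl) {
    data.frame(clade = cl, column = 1:20,
               symbol = sample(cladecons:::AA_LETTERS, 20, replace = TRUE),
               fraction = sample(fractions, 20, replace = TRUE))
  }))
  sim <- simulate_alignment(alignment_spec(c(A = 250, B = 250), 20,
                                           plan, seed = 99))
  tab <- consensus_table(sim$alignment, character_set(1:20),
                         sim$partition, c("A", "B"))
  for (cl in c("A", "B")) {
    truth <- sim$truth[sim$truth$clade == cl, ]
    expect_equal(as.character(tab[[cl]]$tier), truth$tier)
    expect_equal(tab[[cl]]$symbol, truth$realized_top_symbol)
  }
})

test_that("tier censuses partition the character set and aggregate correctly", {
  calls <- mk_calls(1:6, c("G", "G", "A", "-", "#", "V"),
                    c("invariant", "conserved", "highly_conserved",
                      "no_consensus", "absent", "very_highly_conserved"))
  cen <- tier_census(calls)
  expect_equal(sum(cen[tier_levels]), 6L)
  expect_equal(cen[["conserved_plus"]], 3L)
  expect_equal(cen[["invariant"]], 1L)
  all_inv <- mk_calls(1:172, rep("G", 172), rep("invariant", 172))
  expect_equal(tier_census(all_inv)[["invariant"]], 172L)

  set.seed(41)
  aln <- random_alignment(30, 25, gap_prob = 0.1)
  part <- clade_partition(alignment_ids(aln),
                          rep(c("A", "B"), length.out = 30), rep("t", 30))
  tab <- consensus_table(aln, character_set(1:25), part)
  for (cl in names(tab)) {
    expect_equal(sum(tier_census(tab[[cl]])[tier_levels]), 25L)
  }
})
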