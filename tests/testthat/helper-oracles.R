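# Independent oracles and fixture builders used across the suite.

# Brute-force per-column recount: the slow, obviously-correct counterpart of
# profile_columns().
oracle_profile <- function(aln, cs, ids) {
  m <- unclass(aln)[ids, , drop = FALSE]
  lapply(seq_len(nrow(cs)), function(k) {
    counts <- stats::setNames(integer(0), character(0))
    gap <- 0L; x <- 0L
    for (id in rownames(m)) {
      ch <- m[id, cs$column[k]]
      if (ch == "-") gap <- gap + 1L
      else if (ch == "X") x <- x + 1L
      else counts[ch] <- (if (is.na(counts[ch])) 0L else counts[ch]) + 1L
    }
    list(residue_label = cs$label[k],
         counts = counts[order(names(counts))],
         gap_count = gap, x_count = x, n_sequences = nrow(m))
  })
}

# Brute-force scan over all (clade, label) pairs for clade-unique residues.
oracle_unique <- function(tab, clade, min_focal_tier = "consensus",
                          criterion = "not_consensus_elsewhere") {
  lv <- cladecons::tier_levels
  rank <- function(t) match(as.character(t), lv)
  elsewhere <- if (criterion == "not_consensus_elsewhere") "consensus"
               else "weak_consensus"
  focal <- tab[[clade]]
  others <- setdiff(names(tab), c(clade, "All"))
  out <- integer(0)
  for (i in seq_len(nrow(focal))) {
    if (rank(focal$tier[i]) < match(min_focal_tier, lv)) next
    if (!focal$symbol[i] %in% LETTERS) next
    ok <- TRUE
    for (oth in others) {
      row <- tab[[oth]]
      if (row$symbol[i] == focal$symbol[i] &&
          rank(row$tier[i]) >= match(elsewhere, lv)) ok <- FALSE
    }
    if (ok) out <- c(out, focal$residue_label[i])
  }
  out
}

# Exhaustive Dollo oracle: minimal loss count over every single-gain
# assignment of presence/absence to internal nodes.
oracle_dollo_losses <- function(tree, present_tips) {
  n_tip <- ape::Ntip(tree)
  n_node <- tree$Nnode
  tip_state <- tree$tip.label %in% present_tips
  root <- n_tip + 1L
  best <- Inf
  for (mask in 0:(2^n_node - 1)) {
    internal <- as.logical(bitwAnd(mask, 2^(seq_len(n_node) - 1)))
    st <- c(tip_state, internal)
    gains <- sum(st[tree$edge[, 2]] & !st[tree$edge[, 1]]) + st[root]
    if (gains != 1) next
    losses <- sum(!st[tree$edge[, 2]] & st[tree$edge[, 1]])
    if (losses < best) best <- losses
  }
  best
}

# Random aligned amino-acid sequences (optionally with gaps).
random_alignment <- function(n_seq, n_col, gap_prob = 0, x_prob = 0) {
  symbols <- c(cladecons:::AA_LETTERS)
  m <- matrix(sample(symbols, n_seq * n_col, replace = TRUE), n_seq, n_col)
  if (gap_prob > 0) m[runif(length(m)) < gap_prob] <- "-"
  if (x_prob > 0) m[runif(length(m)) < x_prob] <- "X"
  rownames(m) <- sprintf("s%02d", seq_len(n_seq))
  aa_alignment(m)
}

# Assemble a consensus_table object directly from per-clade call rows
# (used to construct exact signature/divergence scenarios).
make_table <- function(rows, labels = NULL) {
  labels <- labels %||% rows[[1]]$residue_label
  structure(rows, class = "consensus_table",
            thresholds = tier_thresholds(), denominator = "all",
            labels = labels)
}

mk_calls <- function(labels, symbols, tiers, top = NULL) {
  data.frame(residue_label = labels, symbol = symbols,
             tier = factor(tiers, levels = cladecons::tier_levels,
                           ordered = TRUE),
             top_fraction = top %||% rep(NA_real_, length(labels)))
}

# A column profile literal for classify_tier tests.
mk_profile <- function(counts, gap = 0L, x = 0L, n = NULL, label = 1L) {
  list(residue_label = label, counts = counts, gap_count = as.integer(gap),
       x_count = as.integer(x),
       n_sequences = n %||% (sum(counts) + gap + x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
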