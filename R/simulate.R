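# Seeded synthetic data: clade-structured alignments with planted
# conservation tiers and clade-unique residues, and presence matrices
# generated from known single-gain / multiple-loss histories on a tree.
#
# The generator plants per-column per-clade consensus structure: the
# planted symbol is assigned to round(fraction * n) randomly chosen
# sequences (realizing the target top fraction to within 1/n) and the rest
# draw a background amino acid, uniform over the 19 non-planted letters —
# the most adversarial background for consensus calling. Gaps are placed
# column-wise and independently; there is no indel model, because every
# analysis under test sees only columns.

#' Specification of a synthetic clade-structured alignment
#'
#' @param clades Named integer vector: clade label -> number of sequences
#'   (each >= 1).
#' @param n_columns Number of alignment columns.
#' @param plan Optional data.frame with columns `clade`, `column`, `symbol`,
#'   `fraction`: at that clade x column, the planted symbol is drawn with
#'   the given target top fraction. Columns without a row for a clade are
#'   `random` (uniform over the 20 amino acids). A planted fraction that the
#'   clade's sample size cannot realize to within one sequence is an error.
#' @param gap Gap plan: a single fraction applied everywhere, or a
#'   data.frame `clade`, `column`, `fraction` (unlisted cells get 0).
#' @param seed Integer seed; the generator is deterministic given the spec.
#'
#' @return A list of class `alignment_spec`.
#' @export
alignment_spec <- function(clades, n_columns, plan = NULL, gap = 0,
                           seed = 1L) {
  if (is.null(names(clades)) || any(names(clades) == "")) {
    stop_cc("clades must be a named vector", class = "cladecons_spec_error")
  }
  if (any(clades < 1)) {
    stop_cc("every clade needs at least one sequence",
            class = "cladecons_spec_error")
  }
  if (!is.null(plan)) {
    need <- c("clade", "column", "symbol", "fraction")
    if (!all(need %in% names(plan))) {
      stop_cc("plan needs columns clade, column, symbol, fraction",
              class = "cladecons_spec_error")
    }
    if (any(!plan$clade %in% names(clades)) ||
        any(plan$column < 1 | plan$column > n_columns) ||
        any(!plan$symbol %in% AA_LETTERS) ||
        any(plan$fraction < 0 | plan$fraction > 1)) {
      stop_cc("plan entries out of range", class = "cladecons_spec_error")
    }
    n_for <- clades[plan$clade]
    infeasible <- plan$fraction > 0 & round(n_for * plan$fraction) == 0
    if (any(infeasible)) {
      stop_cc(sprintf(
        "planted fraction %.3f cannot be realized with %d sequences",
        plan$fraction[infeasible][1], n_for[infeasible][1]),
        class = "cladecons_spec_error")
    }
  }
  structure(list(clades = clades, n_columns = as.integer(n_columns),
                 plan = plan, gap = gap, seed = as.integer(seed)),
            class = "alignment_spec")
}

gap_fraction_for <- function(gap, clade, column) {
  if (is.data.frame(gap)) {
    hit <- gap$clade == clade & gap$column == column
    if (any(hit)) gap$fraction[hit][1] else 0
  } else gap
}

#' Simulate a clade-structured alignment with planted truth
#'
#' @param spec An [alignment_spec()].
#'
#' @return A list of class `simulated_alignment`:
#'   * `alignment`: the `aa_alignment` (ids `<clade>_<i>`);
#'   * `partition`: the matching `clade_partition` (taxon = clade label);
#'   * `truth`: data.frame `clade`, `residue_label`, `planted_symbol` (`NA`
#'     for random columns), `target_fraction`, `realized_top_symbol`,
#'     `realized_top_fraction` (top amino-acid count over all member
#'     sequences, gaps in the denominator), and `tier`, the band implied by
#'     the realized — not the target — fraction (ties and gap-majorities
#'     recorded as `no_consensus`/`absent` by direct band arithmetic).
#' @export
simulate_alignment <- function(spec) {
  stopifnot(inherits(spec, "alignment_spec"))
  set.seed(spec$seed)
  th <- tier_thresholds()
  rows <- list(); ids <- character(); clade_of <- character()
  truth <- list()
  for (cl in names(spec$clades)) {
    n <- spec$clades[[cl]]
    mat <- matrix("", nrow = n, ncol = spec$n_columns)
    for (j in seq_len(spec$n_columns)) {
      pl <- NULL
      if (!is.null(spec$plan)) {
        hit <- spec$plan$clade == cl & spec$plan$column == j
        if (any(hit)) pl <- spec$plan[hit, ][1, ]
      }
      if (is.null(pl)) {
        col <- sample(AA_LETTERS, n, replace = TRUE)
      } else {
        # Realize the target top fraction exactly (to within 1/n): plant
        # round(f * n) copies at random rows, background elsewhere.
        k <- round(pl$fraction * n)
        col <- sample(setdiff(AA_LETTERS, pl$symbol), n, replace = TRUE)
        if (k > 0) col[sample.int(n, k)] <- pl$symbol
      }
      g <- gap_fraction_for(spec$gap, cl, j)
      if (g > 0) col[stats::runif(n) < g] <- "-"
      mat[, j] <- col

      # Truth from realized counts, by direct band arithmetic.
      counts <- table(factor(col, levels = c(AA_LETTERS, "-")))
      gapn <- counts[["-"]]; counts <- counts[AA_LETTERS]
      if (gapn / n > th$absent_gap_fraction) {
        tier <- "absent"; top_sym <- "#"; top_f <- NA_real_
      } else {
        top <- max(counts); top_f <- top / n
        tier <- tier_from_fraction(top_f, th)
        if (sum(counts == top) > 1 && tier != "no_consensus") {
          tier <- "no_consensus"
        }
        top_sym <- if (tier == "no_consensus") "-" else
          names(counts)[which.max(counts)]
      }
      truth[[length(truth) + 1]] <- data.frame(
        clade = cl, residue_label = j,
        planted_symbol = if (is.null(pl)) NA_character_ else pl$symbol,
        target_fraction = if (is.null(pl)) NA_real_ else pl$fraction,
        realized_top_symbol = top_sym, realized_top_fraction = top_f,
        tier = tier)
    }
    rownames(mat) <- sprintf("%s_%03d", cl, seq_len(n))
    rows[[cl]] <- mat
    ids <- c(ids, rownames(mat))
    clade_of <- c(clade_of, rep(cl, n))
  }
  aln <- aa_alignment(do.call(rbind, rows))
  structure(list(alignment = aln,
                 partition = clade_partition(ids, clade_of, clade_of),
                 truth = do.call(rbind, truth)),
            class = "simulated_alignment")
}

#' Specification of a gain/loss history on a tree
#'
#' @param tree A rooted `ape::phylo` taxonomy.
#' @param gains Named character vector: clade label -> name of the node
#'   (tip or internal, see [node_names()]) below whose parent branch the
#'   clade is gained.
#' @param losses Named list: clade label -> character vector of node names;
#'   each named node's subtree loses the clade. Every loss must lie strictly
#'   below the clade's gain, and loss subtrees must be disjoint.
#' @param count_lambda Poisson rate for per-tip sequence counts; surviving
#'   tips receive `1 + rpois(count_lambda)` sequences.
#' @param seed Integer seed.
#'
#' @return A list of class `history_spec`.
#' @export
history_spec <- function(tree, gains, losses = list(), count_lambda = 1,
                         seed = 1L) {
  below <- tips_below(tree)
  for (cl in names(losses)) {
    if (!cl %in% names(gains)) {
      stop_cc("loss listed for clade '", cl, "' without a gain",
              class = "cladecons_spec_error")
    }
    gain_node <- node_id(tree, gains[[cl]])
    loss_nodes <- vapply(losses[[cl]], node_id, integer(1), tree = tree)
    gain_tips <- below[[gain_node]]
    for (ln in loss_nodes) {
      if (ln == gain_node || !all(below[[ln]] %in% gain_tips) ||
          length(below[[ln]]) == length(gain_tips)) {
        stop_cc("loss at '", node_names(tree)[ln],
                "' is not strictly below the gain of clade '", cl, "'",
                class = "cladecons_spec_error")
      }
    }
    if (length(loss_nodes) > 1) {
      sets <- lapply(loss_nodes, function(ln) below[[ln]])
      if (length(unique(unlist(sets))) != length(unlist(sets))) {
        stop_cc("loss subtrees of clade '", cl, "' overlap",
                class = "cladecons_spec_error")
      }
    }
  }
  structure(list(tree = tree, gains = gains, losses = losses,
                 count_lambda = count_lambda, seed = as.integer(seed)),
            class = "history_spec")
}

#' Simulate a presence matrix from a known gain/loss history
#'
#' @param spec A [history_spec()].
#'
#' @return A list of class `simulated_history`: `pm` (a `presence_matrix`
#'   over all tree tips) and `truth` (the planted event list, in the same
#'   shape as `dollo_reconstruct()$events`).
#' @export
simulate_history <- function(spec) {
  stopifnot(inherits(spec, "history_spec"))
  set.seed(spec$seed)
  tree <- spec$tree
  below <- tips_below(tree)
  parent <- tree_parent(tree)
  names_all <- node_names(tree)
  n_tip <- ape::Ntip(tree)
  root <- n_tip + 1L
  clades <- names(spec$gains)
  pm <- matrix(0L, n_tip, length(clades),
               dimnames = list(tree$tip.label, clades))
  truth <- list()
  for (cl in clades) {
    gain_node <- node_id(tree, spec$gains[[cl]])
    alive <- below[[gain_node]]
    truth[[length(truth) + 1]] <- data.frame(
      clade = cl,
      parent = if (gain_node == root) "root" else names_all[parent[gain_node]],
      child = names_all[gain_node], event = "gain")
    for (nm in spec$losses[[cl]]) {
      ln <- node_id(tree, nm)
      alive <- setdiff(alive, below[[ln]])
      truth[[length(truth) + 1]] <- data.frame(
        clade = cl, parent = names_all[parent[ln]], child = names_all[ln],
        event = "loss")
    }
    pm[alive, cl] <- 1L + stats::rpois(length(alive), spec$count_lambda)
  }
  structure(list(pm = structure(pm, class = c("presence_matrix", "matrix")),
                 truth = do.call(rbind, truth)),
            class = "simulated_history")
}
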