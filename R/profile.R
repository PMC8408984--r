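# Per-column conservation profiling and banded tier classification.
#
# Each retained residue is profiled per clade (amino-acid counts, gaps,
# ambiguous symbols) and the top amino-acid fraction is classified into the
# conservation tiers used for family-wide consensus displays:
#   weak consensus  > 30%      consensus        > 50%
#   conserved       > 75%      highly conserved > 90%
#   very highly conserved > 95%   invariant     > 99%
# A residue is called absent ('#') when most sequences are gapped there, and
# no consensus ('-') when no single amino acid rises above the weak band.

#' Conservation tier levels
#'
#' Ordered from least to most conserved; `absent` sorts lowest.
#' @export
tier_levels <- c("absent", "no_consensus", "weak_consensus", "consensus",
                 "conserved", "highly_conserved", "very_highly_conserved",
                 "invariant")

tier_factor <- function(x) factor(x, levels = tier_levels, ordered = TRUE)

#' Conservation tier thresholds
#'
#' Lower bounds (exclusive: a tier requires `f > bound`) for each band of the
#' top amino-acid fraction, plus the gap fraction above which a residue is
#' called absent.
#'
#' @param weak,consensus,conserved,highly,very_highly,invariant Strictly
#'   increasing fractions in `(0, 1]`.
#' @param absent_gap_fraction Gap fraction above which the residue is called
#'   absent (`#`); default 0.5.
#'
#' @return A list of class `tier_thresholds`.
#' @export
tier_thresholds <- function(weak = 0.30, consensus = 0.50, conserved = 0.75,
                            highly = 0.90, very_highly = 0.95,
                            invariant = 0.99, absent_gap_fraction = 0.50) {
  th <- list(weak = weak, consensus = consensus, conserved = conserved,
             highly = highly, very_highly = very_highly,
             invariant = invariant,
             absent_gap_fraction = absent_gap_fraction)
  bands <- unlist(th[1:6])
  if (any(diff(bands) <= 0) || any(bands <= 0) || any(bands > 1)) {
    stop_cc("tier thresholds must be strictly increasing within (0, 1]",
            class = "cladecons_threshold_error")
  }
  structure(th, class = "tier_thresholds")
}

tier_from_fraction <- function(f, th) {
  if (f > th$invariant) "invariant"
  else if (f > th$very_highly) "very_highly_conserved"
  else if (f > th$highly) "highly_conserved"
  else if (f > th$conserved) "conserved"
  else if (f > th$consensus) "consensus"
  else if (f > th$weak) "weak_consensus"
  else "no_consensus"
}

#' Profile the character-set columns of a clade
#'
#' Counts amino acids per column over the member sequences. `X` symbols are
#' treated as missing data: excluded from the amino-acid counts and not
#' counted as gaps.
#'
#' @param aln An `aa_alignment`.
#' @param cs A `character_set` over `aln`.
#' @param member_ids Non-empty set of sequence ids (subset of
#'   `alignment_ids(aln)`).
#'
#' @return A list of class `column_profiles`; one element per character-set
#'   column (in label order), each a list with `residue_label`, `counts`
#'   (named integer over amino acids seen), `gap_count`, `x_count`,
#'   `n_sequences`.
#' @export
profile_columns <- function(aln, cs, member_ids) {
  stopifnot(inherits(aln, "aa_alignment"))
  if (length(member_ids) == 0) {
    stop_cc("member set is empty", class = "cladecons_precondition_error")
  }
  missing_ids <- setdiff(member_ids, rownames(aln))
  if (length(missing_ids) > 0) {
    stop_cc("ids not in alignment: ",
            paste(utils::head(missing_ids, 5), collapse = ", "),
            class = "cladecons_precondition_error")
  }
  sub <- unclass(aln)[member_ids, cs$column, drop = FALSE]
  n <- length(member_ids)
  profiles <- lapply(seq_len(ncol(sub)), function(j) {
    col <- sub[, j]
    tab <- table(factor(col, levels = c(AA_LETTERS, "X", "-")))
    counts <- tab[AA_LETTERS]
    counts <- counts[counts > 0]
    list(residue_label = cs$label[j],
         counts = stats::setNames(as.integer(counts), names(counts)),
         gap_count = as.integer(tab[["-"]]),
         x_count = as.integer(tab[["X"]]),
         n_sequences = n)
  })
  structure(profiles, class = "column_profiles")
}

#' Classify one column profile into a conservation tier
#'
#' The residue is called absent (`#`) when the gap fraction exceeds
#' `th$absent_gap_fraction`. Otherwise the top amino-acid fraction `f` is
#' computed over the chosen denominator and banded: `f <= weak` is no
#' consensus (`-`); each higher band requires `f` strictly above its bound.
#' A tie for the maximum count means no single amino acid can be named, so
#' the call is no consensus.
#'
#' @param profile One element of a [profile_columns()] result.
#' @param th A [tier_thresholds()] object.
#' @param denominator `"all"` (default): fractions are over all member
#'   sequences, gaps included; `"non_gap"`: over sequences carrying an
#'   unambiguous amino acid at the column.
#'
#' @return A one-row data.frame: `residue_label`, `symbol` (amino-acid
#'   letter, `-` or `#`), `tier` (ordered factor over [tier_levels]),
#'   `top_fraction`.
#' @export
classify_tier <- function(profile, th = tier_thresholds(),
                          denominator = c("all", "non_gap")) {
  denominator <- match.arg(denominator)
  n <- profile$n_sequences
  if (profile$gap_count / n > th$absent_gap_fraction) {
    return(data.frame(residue_label = profile$residue_label, symbol = "#",
                      tier = tier_factor("absent"), top_fraction = NA_real_))
  }
  counts <- profile$counts
  denom <- if (denominator == "all") n else
    n - profile$gap_count - profile$x_count
  if (length(counts) == 0 || denom == 0) {
    return(data.frame(residue_label = profile$residue_label, symbol = "-",
                      tier = tier_factor("no_consensus"), top_fraction = 0))
  }
  top <- max(counts)
  f <- top / denom
  tied <- sum(counts == top) > 1
  tier <- tier_from_fraction(f, th)
  if (tied && tier != "no_consensus") {
    cc_log(sprintf(
      "residue %d: tie at top fraction %.3f between {%s}; calling no consensus",
      profile$residue_label, f,
      paste(names(counts)[counts == top], collapse = ",")),
      level = "WARNING", quiet = TRUE)
    tier <- "no_consensus"
  }
  symbol <- if (tier == "no_consensus") "-" else names(counts)[which.max(counts)]
  data.frame(residue_label = profile$residue_label, symbol = symbol,
             tier = tier_factor(tier), top_fraction = f)
}

classify_profiles <- function(profiles, th, denominator) {
  do.call(rbind, lapply(profiles, classify_tier, th = th,
                        denominator = denominator))
}

#' Per-clade consensus table over a character set
#'
#' Computes, for each requested clade, the consensus call at every
#' character-set residue. The pseudo-clade `"All"` may be included in
#' `clades`; it is the union of the other requested clades (or, if none
#' other is requested, of the whole partition).
#'
#' @param aln An `aa_alignment`.
#' @param cs A `character_set` over `aln`.
#' @param partition A `clade_partition` covering (at least) the profiled ids.
#' @param clades Clade labels to profile; default all labels in the
#'   partition. Every clade must be non-empty.
#' @param th A [tier_thresholds()].
#' @param denominator Passed to [classify_tier()].
#'
#' @return A named list of class `consensus_table`, one data.frame of calls
#'   per clade, all sharing the same `residue_label` order. Attributes
#'   record the thresholds and denominator used.
#' @export
consensus_table <- function(aln, cs, partition, clades = NULL,
                            th = tier_thresholds(),
                            denominator = c("all", "non_gap")) {
  denominator <- match.arg(denominator)
  clades <- clades %||% clade_labels(partition)
  real <- setdiff(clades, "All")
  unknown <- setdiff(real, clade_labels(partition))
  if (length(unknown) > 0) {
    stop_cc("unknown clade label(s): ", paste(unknown, collapse = ", "),
            class = "cladecons_partition_error")
  }
  members <- lapply(real, clade_members, partition = partition)
  names(members) <- real
  if ("All" %in% clades) {
    members$All <- if (length(real) > 0) unique(unlist(members))
                   else partition$id
  }
  members <- members[clades]
  empty <- names(members)[lengths(members) == 0]
  if (length(empty) > 0) {
    stop_cc("empty clade(s): ", paste(empty, collapse = ", "),
            class = "cladecons_partition_error")
  }
  rows <- lapply(members, function(ids) {
    classify_profiles(profile_columns(aln, cs, ids), th, denominator)
  })
  structure(rows, class = "consensus_table", thresholds = th,
            denominator = denominator, labels = cs$label)
}

#' @export
print.consensus_table <- function(x, ...) {
  cat(sprintf("consensus table: %d clade(s) x %d residues (denominator: %s)\n",
              length(x), length(attr(x, "labels")), attr(x, "denominator")))
  for (cl in names(x)) {
    cat(sprintf("  %-8s %s\n", cl, paste(x[[cl]]$symbol, collapse = "")))
  }
  invisible(x)
}

#' Census of conservation tiers in one clade row
#'
#' @param calls A data.frame of consensus calls (one clade row of a
#'   [consensus_table()]).
#'
#' @return Named integer vector with one count per tier plus
#'   `conserved_plus`, the aggregate of the conserved, highly conserved and
#'   very highly conserved tiers (the headline "conserved residues" figure of
#'   family conservation summaries). The per-tier counts sum to `nrow(calls)`.
#' @export
tier_census <- function(calls) {
  if (nrow(calls) == 0) {
    stop_cc("empty consensus row", class = "cladecons_precondition_error")
  }
  counts <- table(factor(calls$tier, levels = tier_levels))
  out <- stats::setNames(as.integer(counts), tier_levels)
  c(out, conserved_plus = out[["conserved"]] + out[["highly_conserved"]] +
      out[["very_highly_conserved"]])
}

#' Write a consensus table as TSV
#'
#' One row per residue label; per clade a symbol, tier and top-fraction
#' column.
#'
#' @param tab A `consensus_table`.
#' @param path Output path.
#' @param comments Extra header comment lines.
#' @return `path`, invisibly.
#' @export
write_consensus_table <- function(tab, path, comments = character()) {
  out <- data.frame(residue_label = attr(tab, "labels"))
  for (cl in names(tab)) {
    out[[paste0(cl, ".symbol")]] <- tab[[cl]]$symbol
    out[[paste0(cl, ".tier")]] <- as.character(tab[[cl]]$tier)
    out[[paste0(cl, ".top_fraction")]] <- round(tab[[cl]]$top_fraction, 4)
  }
  th <- attr(tab, "thresholds")
  write_tsv_commented(out, path, c(
    sprintf("tier thresholds: weak>%s consensus>%s conserved>%s highly>%s very_highly>%s invariant>%s absent_gap>%s",
            th$weak, th$consensus, th$conserved, th$highly, th$very_highly,
            th$invariant, th$absent_gap_fraction),
    sprintf("denominator: %s", attr(tab, "denominator")),
    comments))
}
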