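# Clade-unique signature residues, functional-motif annotation, and the
# divergence matrix of focal clades against a reference consensus.

#' Functional motif coordinates
#'
#' Residue-label ranges (reference-protein numbering, conventionally
#' Arabidopsis FT) for the motifs governing floral activation-complex
#' formation, plus the catalogue of key specificity residues. Two published
#' coordinate profiles are shipped because the literature uses both
#' numberings:
#' * `"fig"` (default): 14-3-3 surface parts a/b 60–64 and 95–101,
#'   P-loop 128–140, LYN triad 150–152.
#' * `"text"`: 59–65, 93–100, 127–140, 149–151.
#'
#' @param profile `"fig"` or `"text"`.
#' @param key_residues Integer labels of the key specificity residues
#'   (external-ligand binding, 14-3-3 interaction, P-loop and LYN residues).
#'
#' @return A list of class `motif_map` with elements `ranges` (named list of
#'   integer label vectors) and `key_residues`.
#' @export
motif_map <- function(profile = c("fig", "text"),
                      key_residues = c(60, 61, 62, 64, 66, 85, 94, 96, 97,
                                       101, 130, 134, 138, 140)) {
  profile <- match.arg(profile)
  ranges <- if (profile == "fig") {
    list(fourteen33_a = 60:64, fourteen33_b = 95:101,
         p_loop = 128:140, lyn_triad = 150:152)
  } else {
    list(fourteen33_a = 59:65, fourteen33_b = 93:100,
         p_loop = 127:140, lyn_triad = 149:151)
  }
  structure(list(ranges = ranges, key_residues = as.integer(key_residues),
                 profile = profile),
            class = "motif_map")
}

#' All residue labels covered by a motif map
#' @param motifs A `motif_map`.
#' @return Sorted integer vector of labels.
#' @export
motif_labels <- function(motifs) {
  sort(unique(c(unlist(motifs$ranges), motifs$key_residues)))
}

#' Detect clade-unique conserved residues
#'
#' A residue belongs to a clade's signature set when the clade's own call
#' reaches `min_focal_tier` and its consensus amino acid is not shared, at
#' the comparison level set by `criterion`, by any other clade in the table:
#' * `not_consensus_elsewhere` (default): no other clade has the same symbol
#'   at tier consensus (>50%) or above.
#' * `not_weak_elsewhere`: stricter — the symbol must not even be another
#'   clade's weak consensus (>30%); its signature sets are therefore subsets
#'   of the default's.
#'
#' A pseudo-clade named `"All"` in the table is never used as a comparator
#' (it contains the focal clade by construction).
#'
#' @param tab A [consensus_table()] with at least two clades.
#' @param clade Focal clade label.
#' @param min_focal_tier Minimum focal tier (default `"consensus"`).
#' @param criterion Uniqueness criterion; see above.
#'
#' @return A data.frame of class `signature_set` (`clade`, `residue_label`,
#'   `symbol`, `tier`) with the criterion recorded as attributes.
#' @export
unique_residues <- function(tab, clade, min_focal_tier = "consensus",
                            criterion = c("not_consensus_elsewhere",
                                          "not_weak_elsewhere")) {
  criterion <- match.arg(criterion)
  min_focal_tier <- match.arg(min_focal_tier, tier_levels)
  if (!clade %in% names(tab)) {
    stop_cc("unknown clade '", clade, "' in consensus table",
            class = "cladecons_partition_error")
  }
  others <- setdiff(names(tab), c(clade, "All"))
  if (length(others) == 0) {
    stop_cc("uniqueness needs at least two clades",
            class = "cladecons_precondition_error")
  }
  elsewhere_min <- if (criterion == "not_consensus_elsewhere") "consensus"
                   else "weak_consensus"
  focal <- tab[[clade]]
  keep <- focal$tier >= tier_factor(min_focal_tier) &
    focal$symbol %in% AA_LETTERS
  for (other in others) {
    row <- tab[[other]]
    shared <- row$symbol == focal$symbol &
      row$tier >= tier_factor(elsewhere_min)
    keep <- keep & !shared
  }
  out <- focal[keep, c("residue_label", "symbol", "tier"), drop = FALSE]
  out <- cbind(clade = rep(clade, nrow(out)), out)
  rownames(out) <- NULL
  structure(out, class = c("signature_set", "data.frame"),
            criterion = criterion, min_focal_tier = min_focal_tier)
}

#' Annotate consensus calls with motif membership
#'
#' @param calls A data.frame of consensus calls (one clade row).
#' @param motifs A [motif_map()]. Every motif range must overlap the row's
#'   label range; a range lying wholly outside it indicates a mismatched
#'   coordinate configuration and is an error.
#'
#' @return `calls` with added columns `motifs` (comma-separated motif names,
#'   `""` when none) and `key_residue` (logical).
#' @export
annotate_motifs <- function(calls, motifs) {
  labels <- calls$residue_label
  for (nm in names(motifs$ranges)) {
    if (!any(motifs$ranges[[nm]] %in% labels)) {
      stop_cc("motif '", nm, "' (labels ",
              min(motifs$ranges[[nm]]), "-", max(motifs$ranges[[nm]]),
              ") lies outside the character set",
              class = "cladecons_config_error")
    }
  }
  tag <- vapply(labels, function(lb) {
    paste(names(motifs$ranges)[vapply(motifs$ranges, function(r) lb %in% r,
                                      logical(1))], collapse = ",")
  }, character(1))
  calls$motifs <- tag
  calls$key_residue <- labels %in% motifs$key_residues
  calls
}

# Collapse the full tier scale to the three-band scale used in divergence
# displays (>90 / >75 / >50 / none / absent). Derived from the same
# thresholds object; no second threshold system.
collapse_tier <- function(tier) {
  map <- c(absent = "absent", no_consensus = "no_consensus",
           weak_consensus = "no_consensus", consensus = "consensus",
           conserved = "conserved", highly_conserved = "highly",
           very_highly_conserved = "highly", invariant = "highly")
  unname(map[as.character(tier)])
}

#' Divergence matrix of focal clades against a reference consensus
#'
#' For each selected residue and each focal clade, reports the focal
#' consensus symbol, its conservation on the collapsed three-band scale
#' (`highly` >90%, `conserved` >75%, `consensus` >50%, else
#' `no_consensus`/`absent`), and whether it matches the reference clade's
#' consensus. Residues at which every focal clade matches the reference are
#' omitted, so the grid shows only informative positions; the omission rule
#' never drops a residue at which any focal clade differs.
#'
#' @param tab A [consensus_table()] containing the reference, the focal
#'   clades, and (for the default residue selection) the background clades
#'   against which reference-unique residues are found.
#' @param focal_clades Focal clade labels (e.g. the monocot/grass FT clades).
#' @param reference_clade Reference clade label (e.g. `EuFT`, angiosperm FT
#'   without the monocots). Must not be among the focal clades.
#' @param residue_selection Integer labels to display; default is the union
#'   of the reference clade's unique residues (computed against the
#'   non-focal clades in `tab`) and the motif residues. User-extensible so
#'   positions outside the motif ranges can be added.
#' @param motifs A [motif_map()] for the default selection.
#'
#' @return A long data.frame of class `divergence_matrix`: `clade`,
#'   `residue_label`, `symbol`, `tier` (collapsed scale),
#'   `matches_reference` (logical; `NA` when either symbol is not an amino
#'   acid), plus attributes recording reference symbols and selection.
#' @export
divergence_matrix <- function(tab, focal_clades, reference_clade,
                              residue_selection = NULL,
                              motifs = motif_map()) {
  if (reference_clade %in% focal_clades) {
    stop_cc("reference clade must not be among the focal clades",
            class = "cladecons_precondition_error")
  }
  missing <- setdiff(c(focal_clades, reference_clade), names(tab))
  if (length(missing) > 0) {
    stop_cc("clades absent from consensus table: ",
            paste(missing, collapse = ", "),
            class = "cladecons_partition_error")
  }
  ref <- tab[[reference_clade]]
  if (is.null(residue_selection)) {
    background <- setdiff(names(tab), c(focal_clades, "All"))
    ref_unique <- if (length(background) >= 2) {
      sub <- tab[background]
      attributes(sub) <- attributes(tab)[c("thresholds", "denominator",
                                           "labels")]
      class(sub) <- "consensus_table"
      names(sub) <- background
      unique_residues(sub, reference_clade)$residue_label
    } else integer(0)
    residue_selection <- sort(unique(c(
      ref_unique, intersect(motif_labels(motifs), ref$residue_label))))
  }
  residue_selection <- sort(unique(as.integer(residue_selection)))
  bad <- setdiff(residue_selection, ref$residue_label)
  if (length(bad) > 0) {
    stop_cc("residue label(s) not in table: ", paste(bad, collapse = ", "),
            class = "cladecons_index_error")
  }
  idx <- match(residue_selection, ref$residue_label)
  cells <- do.call(rbind, lapply(focal_clades, function(cl) {
    row <- tab[[cl]][idx, ]
    is_aa <- row$symbol %in% AA_LETTERS & ref$symbol[idx] %in% AA_LETTERS
    data.frame(clade = rep(cl, length(idx)),
               residue_label = row$residue_label,
               symbol = row$symbol,
               tier = collapse_tier(row$tier),
               matches_reference = ifelse(is_aa,
                                          row$symbol == ref$symbol[idx],
                                          NA))
  }))
  # Omit residues identical across the reference and every focal clade.
  all_match <- vapply(residue_selection, function(lb) {
    m <- cells$matches_reference[cells$residue_label == lb]
    all(!is.na(m)) && all(m)
  }, logical(1))
  keep_labels <- residue_selection[!all_match]
  cells <- cells[cells$residue_label %in% keep_labels, , drop = FALSE]
  rownames(cells) <- NULL
  structure(cells, class = c("divergence_matrix", "data.frame"),
            reference_clade = reference_clade,
            reference_symbols = stats::setNames(ref$symbol[idx],
                                                residue_selection),
            residue_selection = residue_selection,
            omitted = residue_selection[all_match])
}

#' Per-clade per-motif integrity summary
#'
#' Summarizes, for each focal clade and motif, how many of the motif's
#' residues match the reference consensus, mismatch it, lack a consensus, or
#' are absent. A motif is flagged `decayed` when every one of its residues is
#' mismatching or without consensus — the pattern expected when a clade has
#' lost the corresponding interaction.
#'
#' A residue counts as a `match` when both clades have at least a consensus
#' (>50%) call with the same amino acid; as a `mismatch` when the focal clade
#' has a consensus amino acid that differs from the reference's (or the
#' reference itself lacks a consensus); as `no_consensus` when the focal call
#' is below the consensus band; and as `absent` when the focal residue is
#' gapped out.
#'
#' @param tab A [consensus_table()].
#' @param focal_clades Focal clade labels.
#' @param reference_clade Reference clade label.
#' @param motifs A [motif_map()].
#'
#' @return A data.frame: `clade`, `motif`, `n_residues`, `match`, `mismatch`,
#'   `no_consensus`, `absent`, `decayed`.
#' @export
motif_integrity_report <- function(tab, focal_clades, reference_clade,
                                   motifs = motif_map()) {
  ref <- tab[[reference_clade]]
  out <- list()
  for (cl in focal_clades) {
    row <- tab[[cl]]
    for (nm in names(motifs$ranges)) {
      idx <- which(ref$residue_label %in% motifs$ranges[[nm]])
      state <- vapply(idx, function(i) {
        if (row$tier[i] == "absent") return("absent")
        if (row$tier[i] < tier_factor("consensus")) return("no_consensus")
        if (ref$tier[i] >= tier_factor("consensus") &&
            ref$symbol[i] == row$symbol[i]) "match" else "mismatch"
      }, character(1))
      tabst <- table(factor(state, levels = c("match", "mismatch",
                                              "no_consensus", "absent")))
      out[[length(out) + 1]] <- data.frame(
        clade = cl, motif = nm, n_residues = length(idx),
        match = as.integer(tabst[["match"]]),
        mismatch = as.integer(tabst[["mismatch"]]),
        no_consensus = as.integer(tabst[["no_consensus"]]),
        absent = as.integer(tabst[["absent"]]),
        decayed = length(idx) > 0 &&
          all(state %in% c("mismatch", "no_consensus")))
    }
  }
  do.call(rbind, out)
}
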