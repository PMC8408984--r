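# Percent identity over a character set.
#
# 'X' (ambiguous) symbols carry no amino-acid identity and are treated as
# missing data in every mode: never counted as matches and excluded from
# denominators that exclude gaps.

is_residue <- function(x) x %in% AA_LETTERS

#' Percent identity of two aligned sequences
#'
#' @param a,b Equal-length gapped sequences: character strings or character
#'   vectors of single symbols (already restricted to the character set).
#' @param mode Gap handling:
#'   * `exclude_any_gap` (default): identity = matches / columns where both
#'     carry an unambiguous residue.
#'   * `gap_mismatch`: denominator = columns where at least one carries a
#'     residue (a gap against a residue counts as a mismatch).
#'   * `gap_gap_match`: shared gaps count as matches, denominator = all
#'     columns.
#'
#' @return Percent identity in `[0, 100]`.
#' @export
#' @examples
#' pairwise_identity("MKLV", "MKIV")  # 75
pairwise_identity <- function(a, b, mode = c("exclude_any_gap",
                                             "gap_mismatch",
                                             "gap_gap_match")) {
  mode <- match.arg(mode)
  if (is.character(a) && length(a) == 1) a <- strsplit(toupper(a), "")[[1]]
  if (is.character(b) && length(b) == 1) b <- strsplit(toupper(b), "")[[1]]
  if (length(a) != length(b)) {
    stop_cc("sequences differ in length", class = "cladecons_identity_error")
  }
  ra <- is_residue(a); rb <- is_residue(b)
  match_res <- ra & rb & a == b
  denom <- switch(mode,
    exclude_any_gap = sum(ra & rb),
    gap_mismatch = sum(ra | rb),
    gap_gap_match = length(a))
  matches <- switch(mode,
    exclude_any_gap = sum(match_res),
    gap_mismatch = sum(match_res),
    gap_gap_match = sum(match_res | (a == "-" & b == "-")))
  if (denom == 0) {
    stop_cc("no comparable columns: identity undefined",
            class = "cladecons_identity_error")
  }
  100 * matches / denom
}

#' Pairwise identity matrix over a character set
#'
#' @param aln An `aa_alignment`.
#' @param cs Optional `character_set` to restrict to first.
#' @param mode Passed to [pairwise_identity()].
#'
#' @return A symmetric numeric matrix (percent), diagonal 100, of class
#'   `identity_matrix`.
#' @export
identity_matrix <- function(aln, cs = NULL,
                            mode = c("exclude_any_gap", "gap_mismatch",
                                     "gap_gap_match")) {
  mode <- match.arg(mode)
  if (!is.null(cs)) aln <- apply_character_set(aln, cs)
  m <- unclass(aln)
  n <- nrow(m)
  out <- matrix(100, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        v <- pairwise_identity(m[i, ], m[j, ], mode = mode)
        out[i, j] <- v
        out[j, i] <- v
      }
    }
  }
  structure(out, class = c("identity_matrix", "matrix"), mode = mode)
}

#' Mean percent identity within or between groups
#'
#' Arithmetic mean of pairwise identities: over all unordered pairs of
#' `ids_a` (within-group mode, requiring at least two sequences), or over
#' all `ids_a` x `ids_b` pairs (cross-group mode).
#'
#' @param aln An `aa_alignment`.
#' @param cs Optional `character_set`.
#' @param ids_a,ids_b Sequence id sets; `ids_b = NULL` selects within-group
#'   mode.
#' @param mode Passed to [pairwise_identity()].
#'
#' @return Mean percent identity.
#' @export
group_identity <- function(aln, cs = NULL, ids_a, ids_b = NULL,
                           mode = c("exclude_any_gap", "gap_mismatch",
                                    "gap_gap_match")) {
  mode <- match.arg(mode)
  if (!is.null(cs)) aln <- apply_character_set(aln, cs)
  m <- unclass(aln)
  missing_ids <- setdiff(c(ids_a, ids_b), rownames(m))
  if (length(missing_ids) > 0) {
    stop_cc("ids not in alignment: ", paste(missing_ids, collapse = ", "),
            class = "cladecons_precondition_error")
  }
  if (is.null(ids_b)) {
    if (length(ids_a) < 2) {
      stop_cc("within-group identity needs at least two sequences",
              class = "cladecons_precondition_error")
    }
    pairs <- utils::combn(ids_a, 2)
    vals <- apply(pairs, 2, function(p) {
      pairwise_identity(m[p[1], ], m[p[2], ], mode = mode)
    })
  } else {
    if (length(ids_a) == 0 || length(ids_b) == 0) {
      stop_cc("groups must be non-empty",
              class = "cladecons_precondition_error")
    }
    vals <- as.vector(outer(ids_a, ids_b, Vectorize(function(i, j) {
      pairwise_identity(m[i, ], m[j, ], mode = mode)
    })))
  }
  mean(vals)
}

#' Write an identity matrix as TSV
#'
#' Values are reported to one decimal place.
#'
#' @param im An `identity_matrix`.
#' @param path Output path.
#' @param comments Extra header comment lines.
#' @return `path`, invisibly.
#' @export
write_identity_matrix <- function(im, path, comments = character()) {
  df <- data.frame(id = rownames(im),
                   round(unclass(im), 1), check.names = FALSE)
  write_tsv_commented(df, path,
                      c(sprintf("identity mode: %s", attr(im, "mode")),
                        comments))
}
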