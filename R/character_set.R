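# Character sets: the ordered subset of alignment columns retained for all
# quantitative analyses, with residue labels on a reference numbering
# (conventionally 1-based Arabidopsis FT coordinates).

#' Construct a character set
#'
#' @param columns Strictly increasing 1-based column indices into a parent
#'   alignment.
#' @param labels Residue labels, one per column (defaults to `1..k`);
#'   typically 1-based positions in a reference protein such as Arabidopsis
#'   FT. Must be unique.
#'
#' @return A data.frame of class `character_set` with columns `column` and
#'   `label`.
#' @export
character_set <- function(columns, labels = NULL) {
  columns <- as.integer(columns)
  if (length(columns) == 0) {
    stop_cc("character set is empty", class = "cladecons_charset_error")
  }
  if (any(diff(columns) <= 0) || any(columns < 1)) {
    stop_cc("character-set columns must be strictly increasing and >= 1",
            class = "cladecons_charset_error")
  }
  labels <- if (is.null(labels)) seq_along(columns) else as.integer(labels)
  if (length(labels) != length(columns) || anyDuplicated(labels)) {
    stop_cc("labels must be unique and match the number of columns",
            class = "cladecons_charset_error")
  }
  structure(data.frame(column = columns, label = labels),
            class = c("character_set", "data.frame"))
}

#' Derive a character set by column occupancy
#'
#' Keeps columns whose non-gap fraction is at least `min_occupancy`
#' (`X` counts as occupied). This automates the manual trimming to a core of
#' well-represented residues that family-wide conservation analyses rest on;
#' a hand-curated set can instead be loaded with [read_character_set()].
#'
#' @param aln An `aa_alignment`.
#' @param min_occupancy Minimum non-gap fraction in `(0, 1]`; default 0.8.
#' @param reference_id Optional id of a sequence in `aln`; when given, labels
#'   are the 1-based residue numbers of the kept columns in that (ungapped)
#'   reference. Every kept column must then carry a reference residue.
#'
#' @return A `character_set`.
#' @export
derive_character_set <- function(aln, min_occupancy = 0.8,
                                 reference_id = NULL) {
  stopifnot(inherits(aln, "aa_alignment"))
  if (!is.numeric(min_occupancy) || min_occupancy <= 0 || min_occupancy > 1) {
    stop_cc("min_occupancy must lie in (0, 1]",
            class = "cladecons_precondition_error")
  }
  occ <- colMeans(unclass(aln) != "-")
  keep <- which(occ >= min_occupancy)
  if (length(keep) == 0) {
    stop_cc(sprintf("no column reaches occupancy %.2f", min_occupancy),
            class = "cladecons_charset_error")
  }
  cs <- character_set(keep)
  if (!is.null(reference_id)) cs <- label_by_reference(aln, cs, reference_id)
  cs
}

#' Relabel a character set by a reference sequence
#'
#' Assigns each kept column the residue number it carries in an ungapped
#' reference sequence present in the alignment, fixing the coordinate
#' convention (e.g. Arabidopsis FT numbering) used throughout downstream
#' reports.
#'
#' @param aln The parent `aa_alignment`.
#' @param cs A `character_set` over `aln`.
#' @param reference_id Id of the reference sequence.
#'
#' @return The relabelled `character_set`.
#' @export
label_by_reference <- function(aln, cs, reference_id) {
  if (!reference_id %in% rownames(aln)) {
    stop_cc("reference sequence '", reference_id, "' not in alignment",
            class = "cladecons_charset_error")
  }
  ref <- unclass(aln)[reference_id, ]
  num <- cumsum(ref != "-")
  gapped <- ref[cs$column] == "-"
  if (any(gapped)) {
    stop_cc(sprintf(
      "reference '%s' has a gap at %d kept column(s) (first: column %d); cannot number them",
      reference_id, sum(gapped), cs$column[which(gapped)[1]]),
      class = "cladecons_charset_error")
  }
  character_set(cs$column, num[cs$column])
}

#' Restrict an alignment to a character set
#'
#' @param aln An alignment.
#' @param cs A `character_set`; all columns must exist in `aln`.
#'
#' @return An alignment of the same class with `nrow(cs)` columns, in
#'   character-set order.
#' @export
apply_character_set <- function(aln, cs) {
  if (max(cs$column) > ncol(aln)) {
    stop_cc(sprintf("character-set column %d exceeds alignment length %d",
                    max(cs$column), ncol(aln)),
            class = "cladecons_index_error")
  }
  out <- unclass(aln)[, cs$column, drop = FALSE]
  structure(out, class = class(aln))
}

#' Expand an amino-acid character set to codon coordinates
#'
#' @param cs A `character_set` on amino-acid columns.
#' @return A `character_set` on the corresponding nucleotide columns
#'   (three per residue); labels are sequential.
#' @export
codon_expand <- function(cs) {
  nt <- as.vector(rbind(3L * cs$column - 2L, 3L * cs$column - 1L,
                        3L * cs$column))
  character_set(nt)
}

#' Read a character set from TSV
#'
#' Expects a header line `column<TAB>label` with 1-based column indices.
#'
#' @param path Path to the TSV file.
#' @return A `character_set`.
#' @export
read_character_set <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!all(c("column", "label") %in% names(df))) {
    stop_cc("character-set file must have columns 'column' and 'label'",
            class = "cladecons_io_error")
  }
  character_set(df$column, df$label)
}

#' Write a character set as TSV
#' @param cs A `character_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_character_set <- function(cs, path) {
  write_tsv_commented(as.data.frame(cs), path)
}
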