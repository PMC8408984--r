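# Alignment containers and FASTA I/O.
#
# Alignments are stored as character matrices (one row per sequence, one
# column per alignment column, single upper-case symbols) with unique row
# names; this makes per-column profiling, character-set slicing and identity
# computation direct matrix operations.

validate_alignment_symbols <- function(mat, allowed, what) {
  bad <- !(mat %in% allowed)
  if (any(bad)) {
    idx <- which(matrix(bad, nrow = nrow(mat)), arr.ind = TRUE)[1, ]
    stop_cc(sprintf(
      "illegal %s symbol '%s' in sequence '%s' at column %d",
      what, mat[idx[1], idx[2]], rownames(mat)[idx[1]], idx[2]),
      class = "cladecons_alphabet_error")
  }
  invisible(TRUE)
}

as_aln_matrix <- function(seqs) {
  if (is.matrix(seqs)) {
    mat <- toupper(seqs)
  } else {
    ids <- names(seqs)
    if (is.null(ids) || any(ids == "") || anyNA(ids)) {
      stop_cc("sequences must be named with non-empty ids",
              class = "cladecons_alignment_error")
    }
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1) {
      stop_cc(sprintf(
        "sequences are not aligned: lengths range from %d to %d (e.g. '%s')",
        min(lens), max(lens), ids[which.max(lens != lens[1])]),
        class = "cladecons_alignment_error")
    }
    mat <- matrix(unlist(strsplit(toupper(seqs), "", fixed = TRUE)),
                  nrow = length(seqs), byrow = TRUE,
                  dimnames = list(ids, NULL))
  }
  if (anyDuplicated(rownames(mat))) {
    stop_cc("duplicate sequence ids: ",
            paste(unique(rownames(mat)[duplicated(rownames(mat))]),
                  collapse = ", "),
            class = "cladecons_alignment_error")
  }
  mat
}

#' Construct a gapped amino-acid alignment
#'
#' @param seqs A named character vector of equal-length gapped amino-acid
#'   strings, or a character matrix of single symbols with sequence ids as
#'   row names. Allowed symbols are the 20 standard amino acids, `X`
#'   (ambiguous/untranslatable) and `-` (gap); case-insensitive.
#'
#' @return A character matrix of class `aa_alignment`.
#' @export
#' @examples
#' aln <- aa_alignment(c(a = "MK-", b = "ML-"))
#' alignment_length(aln)
aa_alignment <- function(seqs) {
  mat <- as_aln_matrix(seqs)
  validate_alignment_symbols(mat, c(AA_LETTERS, "X", "-"), "amino-acid")
  structure(mat, class = c("aa_alignment", "cc_alignment"))
}

#' Construct a gapped nucleotide alignment
#'
#' @param seqs A named character vector of equal-length gapped nucleotide
#'   strings (alphabet `ACGTN-`, case-insensitive), or an equivalent
#'   character matrix.
#'
#' @details Codon-aligned nucleotide alignments (length divisible by three,
#'   gaps in whole-codon runs) are the substrate of
#'   [translate_alignment()]; the frame requirement is checked there, not at
#'   construction, so non-coding alignments remain representable.
#'
#' @return A character matrix of class `nt_alignment`.
#' @export
nt_alignment <- function(seqs) {
  mat <- as_aln_matrix(seqs)
  validate_alignment_symbols(mat, c(NT_LETTERS, "-"), "nucleotide")
  structure(mat, class = c("nt_alignment", "cc_alignment"))
}

#' @export
print.cc_alignment <- function(x, ...) {
  kind <- if (inherits(x, "aa_alignment")) "amino-acid" else "nucleotide"
  cat(sprintf("%s alignment: %d sequences x %d columns\n",
              kind, nrow(x), ncol(x)))
  invisible(x)
}

#' Number of columns in an alignment
#' @param aln An `aa_alignment` or `nt_alignment`.
#' @return Integer column count.
#' @export
alignment_length <- function(aln) ncol(aln)

#' Sequence ids of an alignment
#' @param aln An `aa_alignment` or `nt_alignment`.
#' @return Character vector of ids in alignment order.
#' @export
alignment_ids <- function(aln) rownames(aln)

#' Collapse an alignment back to gapped strings
#' @param aln An alignment.
#' @return Named character vector of gapped sequences.
#' @export
alignment_strings <- function(aln) {
  stats::setNames(apply(unclass(aln), 1, paste, collapse = ""), rownames(aln))
}

#' Read an aligned FASTA file
#'
#' Sequence ids are the header token up to the first whitespace (the long
#' descriptive headers common in curated family datasets are truncated to
#' their leading accession). Sequences are upper-cased; blank lines are
#' ignored. All records must have equal length.
#'
#' @param path Path to an aligned FASTA file.
#' @param alphabet `"aa"` for amino acids, `"nt"` for nucleotides.
#'
#' @return An `aa_alignment` or `nt_alignment`.
#' @export
read_fasta_alignment <- function(path, alphabet = c("aa", "nt")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) {
    stop_cc("no such file: ", path, class = "cladecons_io_error")
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    stop_cc("no FASTA records in ", path, class = "cladecons_io_error")
  }
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (alphabet == "aa") aa_alignment(seqs) else nt_alignment(seqs)
}

#' Write an alignment as FASTA
#'
#' Sequences are wrapped at 60 columns.
#'
#' @param aln An alignment.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path) {
  set <- Biostrings::BStringSet(alignment_strings(aln))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Translate a codon alignment to amino acids
#'
#' Translation uses the standard genetic code. A whole-gap codon (`---`)
#' becomes a gap; a codon containing `N` or a partial gap becomes `X`
#' (transcriptome-derived fragments make mixed codons common, so they are
#' tolerated rather than rejected); a stop codon is translated as `X` with a
#' warning.
#'
#' @param aln An `nt_alignment` whose length is divisible by three.
#'
#' @return An `aa_alignment` of length `ncol(aln) / 3`.
#' @export
#' @examples
#' translate_alignment(nt_alignment(c(s = "ATGAAA")))
translate_alignment <- function(aln) {
  stopifnot(inherits(aln, "nt_alignment"))
  L <- ncol(aln)
  if (L %% 3L != 0L) {
    stop_cc(sprintf("alignment length %d is not divisible by 3", L),
            class = "cladecons_frame_error")
  }
  code <- Biostrings::GENETIC_CODE
  m <- unclass(aln)
  k <- L %/% 3L
  codons <- matrix("", nrow = nrow(m), ncol = k, dimnames = list(rownames(m)))
  for (j in seq_len(k)) {
    codons[, j] <- paste0(m[, 3L * j - 2L], m[, 3L * j - 1L], m[, 3L * j])
  }
  aa <- code[codons]
  n_mixed <- sum(is.na(aa) & codons != "---")
  if (n_mixed > 0) {
    cc_log(sprintf("%d codon(s) with N or partial gap translated as 'X'",
                   n_mixed), level = "WARNING")
  }
  aa[codons == "---"] <- "-"
  aa[is.na(aa)] <- "X"                       # N-containing or partial-gap codon
  n_stop <- sum(aa == "*")
  if (n_stop > 0) {
    warning(sprintf("%d stop codon(s) translated as 'X'", n_stop),
            call. = FALSE)
    aa[aa == "*"] <- "X"
  }
  dim(aa) <- dim(codons)
  rownames(aa) <- rownames(m)
  aa_alignment(aa)
}
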