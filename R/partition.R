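# Clade partitions: which clade and taxon each sequence belongs to.
# Clade definitions are taken as input labels (from curated phylogenetic
# work), never inferred here.

#' Construct a clade partition
#'
#' @param id Sequence ids (unique, non-empty).
#' @param clade Clade label per sequence (non-empty), e.g. `AnFT`, `AnTCB`,
#'   `NaMFT`, `FT1`..`FT15`.
#' @param taxon Taxon label per sequence (species, order or lineage).
#'
#' @return A data.frame of class `clade_partition` with columns `id`,
#'   `clade`, `taxon`.
#' @export
clade_partition <- function(id, clade, taxon) {
  id <- as.character(id); clade <- as.character(clade)
  taxon <- as.character(taxon)
  if (length(clade) != length(id) || length(taxon) != length(id)) {
    stop_cc("id, clade and taxon must have equal length",
            class = "cladecons_partition_error")
  }
  if (anyDuplicated(id)) {
    stop_cc("duplicate sequence id(s): ",
            paste(unique(id[duplicated(id)]), collapse = ", "),
            class = "cladecons_partition_error")
  }
  if (any(id == "") || any(clade == "") || anyNA(id) || anyNA(clade)) {
    stop_cc("ids and clade labels must be non-empty",
            class = "cladecons_partition_error")
  }
  structure(data.frame(id = id, clade = clade, taxon = taxon),
            class = c("clade_partition", "data.frame"))
}

#' Read a clade partition from TSV
#'
#' Expects a header `id<TAB>clade<TAB>taxon`. One assignment per id;
#' duplicate ids are an error.
#'
#' @param path Path to the TSV file.
#' @return A `clade_partition`.
#' @export
read_partition <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("id", "clade", "taxon")
  if (!all(need %in% names(df))) {
    stop_cc("partition file must have columns id, clade, taxon (got: ",
            paste(names(df), collapse = ", "), ")",
            class = "cladecons_io_error")
  }
  clade_partition(df$id, df$clade, df$taxon)
}

#' Sequence ids belonging to a clade
#'
#' @param partition A `clade_partition`.
#' @param clade A clade label present in the partition, or `"All"` for every
#'   sequence.
#' @return Character vector of ids.
#' @export
clade_members <- function(partition, clade) {
  if (identical(clade, "All")) return(partition$id)
  if (!clade %in% partition$clade) {
    stop_cc("unknown clade label '", clade, "'",
            class = "cladecons_partition_error")
  }
  partition$id[partition$clade == clade]
}

#' Clade labels present in a partition
#' @param partition A `clade_partition`.
#' @return Character vector of unique clade labels, in order of appearance.
#' @export
clade_labels <- function(partition) unique(partition$clade)
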