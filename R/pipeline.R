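# Pipeline front end: configuration, stage execution, manifest and log.

#' Build a run configuration
#'
#' @param alignment Path to the aligned FASTA (alphabet per `alphabet`).
#' @param partition Path to the id/clade/taxon TSV.
#' @param alphabet `"aa"` or `"nt"` (nucleotide alignments are translated).
#' @param charset Optional path to a character-set TSV; when `NULL` one is
#'   derived at `min_occupancy`.
#' @param reference_numbering Optional id of the sequence fixing residue
#'   numbering (e.g. the Arabidopsis FT entry).
#' @param tree Optional Newick taxonomy path (enables the complement stage).
#' @param stages Stages to run, a subset of
#'   `c("profile", "census", "signatures", "diverge", "identity",
#'   "complement")`.
#' @param clades Clade labels to profile (default: all, plus `"All"`).
#' @param reference_clade Reference clade for the divergence stage (default
#'   `"EuFT"`).
#' @param focal_clades Focal clades for the divergence stage (default: all
#'   clades except the reference).
#' @param thresholds A [tier_thresholds()].
#' @param denominator Consensus denominator, `"all"` or `"non_gap"`.
#' @param identity_mode Gap mode for identity, see [pairwise_identity()].
#' @param criterion Uniqueness criterion, see [unique_residues()].
#' @param motifs `"fig"` or `"text"` motif coordinate profile.
#' @param unreliable_absence Taxa excluded from loss inference.
#' @param min_occupancy Occupancy threshold when deriving a character set.
#' @param seed Integer seed recorded in the manifest.
#' @param out Output directory (created if needed).
#'
#' @return A list of class `run_config`.
#' @export
run_config <- function(alignment, partition, alphabet = "aa",
                       charset = NULL, reference_numbering = NULL,
                       tree = NULL,
                       stages = c("profile", "census", "signatures",
                                  "diverge", "identity", "complement"),
                       clades = NULL, reference_clade = "EuFT",
                       focal_clades = NULL,
                       thresholds = tier_thresholds(),
                       denominator = "all",
                       identity_mode = "exclude_any_gap",
                       criterion = "not_consensus_elsewhere",
                       motifs = "fig", unreliable_absence = character(),
                       min_occupancy = 0.8, seed = 1L, out = "cladecons_run") {
  stages <- match.arg(stages, several.ok = TRUE)
  for (p in c(alignment, partition, charset, tree)) {
    if (!is.null(p) && !file.exists(p)) {
      stop_cc("configured file does not exist: ", p,
              class = "cladecons_config_error")
    }
  }
  if ("complement" %in% stages && is.null(tree)) {
    stages <- setdiff(stages, "complement")
  }
  structure(list(alignment = alignment, partition = partition,
                 alphabet = alphabet, charset = charset,
                 reference_numbering = reference_numbering, tree = tree,
                 stages = stages, clades = clades,
                 reference_clade = reference_clade,
                 focal_clades = focal_clades, thresholds = thresholds,
                 denominator = denominator, identity_mode = identity_mode,
                 criterion = criterion, motifs = motifs,
                 unreliable_absence = unreliable_absence,
                 min_occupancy = min_occupancy, seed = as.integer(seed),
                 out = out),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Keys mirror the arguments of [run_config()]; `thresholds` may be a
#' mapping of band names to fractions.
#'
#' @param path Path to the YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$thresholds)) y$thresholds <- do.call(tier_thresholds,
                                                      y$thresholds)
  if (!is.null(y$stages)) y$stages <- unlist(y$stages)
  do.call(run_config, y)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages — consensus profiling, tier censuses,
#' clade-unique signatures, divergence matrix, identity matrix, Dollo
#' complement reconstruction — and writes their TSV outputs, a
#' machine-readable JSON manifest (inputs, parameter values, package
#' version, seed) and a log into the output directory. Identical
#' configurations produce identical outputs (timestamps appear only inside
#' the log). Any stage error aborts with the stage name in the error.
#'
#' @param config A [run_config()].
#' @param quiet Suppress console log lines.
#'
#' @return The output directory path, invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(config$out, "run.log")
  if (file.exists(logfile)) unlink(logfile)
  say <- function(msg, level = "INFO") cc_log(msg, level, logfile, quiet)
  stage <- "setup"
  written <- character()
  result <- tryCatch({
    say(sprintf("reading alignment %s (%s)", config$alignment,
                config$alphabet))
    aln <- read_fasta_alignment(config$alignment, config$alphabet)
    if (config$alphabet == "nt") aln <- translate_alignment(aln)
    part <- read_partition(config$partition)
    cs <- if (!is.null(config$charset)) read_character_set(config$charset)
          else derive_character_set(aln, config$min_occupancy)
    if (!is.null(config$reference_numbering)) {
      cs <- label_by_reference(aln, cs, config$reference_numbering)
    }
    clades <- config$clades %||% c(clade_labels(part), "All")
    param_line <- sprintf(
      "denominator=%s identity_mode=%s criterion=%s motifs=%s seed=%d",
      config$denominator, config$identity_mode, config$criterion,
      config$motifs, config$seed)
    motifs <- motif_map(config$motifs)
    tab <- NULL
    if (any(c("profile", "census", "signatures", "diverge") %in%
            config$stages)) {
      stage <- "profile"
      tab <- consensus_table(aln, cs, part, clades, config$thresholds,
                             config$denominator)
    }
    if ("profile" %in% config$stages) {
      f <- file.path(config$out, "consensus_table.tsv")
      write_consensus_table(tab, f, param_line)
      written <- c(written, f); say("wrote consensus_table.tsv")
    }
    if ("census" %in% config$stages) {
      stage <- "census"
      cen <- do.call(rbind, lapply(names(tab), function(cl) {
        data.frame(clade = cl, t(tier_census(tab[[cl]])))
      }))
      f <- file.path(config$out, "tier_census.tsv")
      write_tsv_commented(cen, f, param_line)
      written <- c(written, f); say("wrote tier_census.tsv")
    }
    if ("signatures" %in% config$stages) {
      stage <- "signatures"
      real <- setdiff(names(tab), "All")
      sig <- do.call(rbind, lapply(real, function(cl) {
        unique_residues(tab, cl, criterion = config$criterion)
      }))
      f <- file.path(config$out, "signatures.tsv")
      write_tsv_commented(sig, f,
                          c(param_line,
                            sprintf("criterion=%s min_focal_tier=consensus",
                                    config$criterion)))
      written <- c(written, f); say("wrote signatures.tsv")
    }
    if ("diverge" %in% config$stages) {
      stage <- "diverge"
      if (!config$reference_clade %in% names(tab)) {
        stop_cc("reference clade '", config$reference_clade,
                "' not profiled", class = "cladecons_config_error")
      }
      focal <- config$focal_clades %||%
        setdiff(names(tab), c(config$reference_clade, "All"))
      div <- divergence_matrix(tab, focal, config$reference_clade,
                               motifs = motifs)
      f <- file.path(config$out, "divergence.tsv")
      write_tsv_commented(as.data.frame(div), f, param_line)
      written <- c(written, f); say("wrote divergence.tsv")
    }
    if ("identity" %in% config$stages) {
      stage <- "identity"
      im <- identity_matrix(aln, cs, config$identity_mode)
      f <- file.path(config$out, "identity_matrix.tsv")
      write_identity_matrix(im, f, param_line)
      written <- c(written, f); say("wrote identity_matrix.tsv")
    }
    if ("complement" %in% config$stages) {
      stage <- "complement"
      tree <- ape::read.tree(config$tree)
      pm <- presence_matrix(part)
      rec <- dollo_reconstruct(tree, pm, config$unreliable_absence)
      f <- file.path(config$out, "complement_events.tsv")
      write_complement(rec, f,
                       file.path(config$out, "complement_annotated.nwk"),
                       param_line)
      written <- c(written, f,
                   file.path(config$out, "complement_annotated.nwk"))
      say("wrote complement_events.tsv")
    }
    stage <- "manifest"
    manifest <- list(
      package = "cladecons",
      version = as.character(utils::packageVersion("cladecons")),
      inputs = list(alignment = config$alignment,
                    partition = config$partition,
                    charset = config$charset, tree = config$tree),
      parameters = list(alphabet = config$alphabet,
                        denominator = config$denominator,
                        identity_mode = config$identity_mode,
                        criterion = config$criterion,
                        motifs = config$motifs,
                        min_occupancy = config$min_occupancy,
                        thresholds = unclass(config$thresholds),
                        reference_clade = config$reference_clade,
                        seed = config$seed),
      stages = config$stages,
      outputs = basename(written))
    jsonlite::write_json(manifest, file.path(config$out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    say("wrote manifest.json")
    invisible(config$out)
  }, cladecons_error = function(e) {
    say(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
        "ERROR")
    stop_cc(sprintf("pipeline stage '%s' failed: %s", stage,
                    conditionMessage(e)),
            class = "cladecons_pipeline_error")
  })
  invisible(config$out)
}
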