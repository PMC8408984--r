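# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# The twenty standard amino acids, in alphabetical one-letter order.
AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

NT_LETTERS <- c("A", "C", "G", "T", "N")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cc <- function(..., class) {
  stop(structure(class = c(class, "cladecons_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Lightweight logger: console via message(), optional file sink.
cc_log <- function(msg, level = "INFO", logfile = NULL, quiet = FALSE) {
  line <- sprintf("[%s] %s", level, msg)
  if (!quiet) message(line)
  if (!is.null(logfile)) {
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), line, "\n",
        sep = "", file = logfile, append = TRUE)
  }
  invisible(line)
}

# Write a data.frame as TSV with '#'-prefixed header comment lines recording
# the parameters that produced it.
write_tsv_commented <- function(x, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) cat("# ", cm, "\n", sep = "", file = con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
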