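# internal helpers

stop_slimscan <- function(msg, class) {
  stop(structure(class = c(class, "slimscan_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# write a data.frame as TSV with '# key: value' provenance header lines
write_tsv_prov <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(provenance)) {
    writeLines(sprintf("# %s: %s", names(provenance),
                       vapply(provenance, paste, "", collapse = ",")), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_prov <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
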