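# Sequence records and residue spans.  All residue coordinates in the
# package are 1-based and inclusive, matching protein residue numbering
# (W99, S744, ...).

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

#' Create a residue span
#'
#' A 1-based inclusive interval on a protein sequence, used for tails,
#' bait domains, fragments and motifs.
#'
#' @param start first residue index (1-based, inclusive).
#' @param end last residue index (1-based, inclusive); must be `>= start`.
#' @return An object of class `span` with fields `start` and `end`.
#' @examples
#' span(63, 101)            # a 39-residue tail
#' span_length(span(63, 101))
#' @export
span <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (length(start) != 1L || length(end) != 1L || is.na(start) || is.na(end))
    stop_slimscan("span start/end must be single integers", "slimscan_bounds_error")
  if (start < 1L || end < start)
    stop_slimscan(sprintf("invalid span (%d,%d): need 1 <= start <= end", start, end),
                  "slimscan_bounds_error")
  structure(list(start = start, end = end), class = "span")
}

#' @rdname span
#' @param x a `span`.
#' @export
span_length <- function(x) x$end - x$start + 1L

#' @export
print.span <- function(x, ...) {
  cat(sprintf("<span %d-%d (length %d)>\n", x$start, x$end, span_length(x)))
  invisible(x)
}

as_span <- function(x) {
  if (inherits(x, "span")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(span(x[1], x[2]))
  stop_slimscan("cannot interpret object as a span", "slimscan_bounds_error")
}

#' Construct a sequence record
#'
#' @param id record identifier.
#' @param residues character vector of one-letter amino-acid codes, or a
#'   single string; uppercased on input.  `X` is accepted as unknown.
#' @param offset global 1-based index of the first residue (default 1);
#'   subsequences carry the offset of their origin.
#' @return Object of class `seq_record` with fields `id`, `residues`
#'   (character vector, one element per residue) and `offset`.
#' @export
seq_record <- function(id, residues, offset = 1L) {
  if (length(residues) == 1L && nchar(residues) > 1L)
    residues <- strsplit(residues, "")[[1]]
  residues <- toupper(residues)
  bad <- which(!residues %in% AA_ALPHABET)
  if (length(bad))
    stop_slimscan(sprintf("record '%s': non-amino-acid character '%s' at position %d",
                          id, residues[bad[1]], bad[1]),
                  "slimscan_format_error")
  if (length(residues) < 1L)
    stop_slimscan(sprintf("record '%s' is empty", id), "slimscan_format_error")
  structure(list(id = as.character(id), residues = residues,
                 offset = as.integer(offset)),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record %s: %d aa, offset %d>\n", x$id,
              length(x$residues), x$offset))
  invisible(x)
}

#' @export
length.seq_record <- function(x) length(x$residues)

#' Parse a FASTA file of protein sequences
#'
#' Reads a multi-record FASTA file (wrapped or unwrapped lines) into a
#' list of [seq_record()] objects.  Residues are uppercased; whitespace is
#' stripped; record order is preserved.
#'
#' @param path path to a FASTA file.
#' @return Named list of `seq_record`s (names are the record ids).
#' @examples
#' fa <- parse_fasta(slimscan_fasta())
#' names(fa)
#' fa$BmGtsf1L$residues[99]   # "W"
#' @export
parse_fasta <- function(path) {
  if (!file.exists(path))
    stop_slimscan(sprintf("FASTA file not found: %s", path), "slimscan_format_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    stop_slimscan(sprintf("empty FASTA file: %s", path), "slimscan_format_error")
  if (!startsWith(lines[1], ">"))
    stop_slimscan(sprintf("%s line 1: expected '>' header, got '%s'", path, lines[1]),
                  "slimscan_format_error")
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = FALSE,
                             forceDNAtolower = FALSE)
  ids <- names(seqs)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop_slimscan(sprintf("%s: duplicate record id(s): %s", path,
                          paste(unique(dup), collapse = ", ")),
                  "slimscan_format_error")
  out <- lapply(seq_along(seqs), function(i) {
    res <- toupper(as.character(seqs[[i]]))
    res <- res[res != "*"]
    bad <- which(!res %in% AA_ALPHABET)
    if (length(bad))
      stop_slimscan(sprintf("%s, record '%s': invalid residue character '%s' (position %d)",
                            path, ids[i], res[bad[1]], bad[1]),
                    "slimscan_format_error")
    seq_record(ids[i], res)
  })
  names(out) <- ids
  out
}

#' Write sequence records as FASTA
#'
#' @param records list of `seq_record`s.
#' @param path output file.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    writeLines(paste0(">", r$id), con)
    s <- paste(r$residues, collapse = "")
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Path to the packaged BmGtsf1L/BmVreteno FASTA fixture
#'
#' Full-length sequences of the silkworm proteins BmGtsf1L (101 aa; the
#' C-terminal tail carries the tryptophan-anchored motif) and BmVreteno
#' (1063 aa; carries the three extended Tudor domains).
#'
#' @return File path of the installed FASTA fixture.
#' @export
slimscan_fasta <- function() {
  system.file("extdata", "gtsf1l_vreteno.fasta", package = "slimscan",
              mustWork = TRUE)
}

#' Extract a subsequence
#'
#' Returns the residues of `record` within `sp` as a new record whose
#' `offset` remembers the global coordinate of its first residue, so that
#' residue numbering stays consistent with the full-length sequence.
#'
#' @param record a [seq_record()].
#' @param sp a [span()] in the record's global coordinates.
#' @return A `seq_record` covering `sp`.
#' @examples
#' fa <- parse_fasta(slimscan_fasta())
#' paste(subsequence(fa$BmGtsf1L, span(97, 101))$residues, collapse = "")  # "EIWDD"
#' @export
subsequence <- function(record, sp) {
  sp <- as_span(sp)
  lo <- record$offset
  hi <- record$offset + length(record$residues) - 1L
  if (sp$start < lo || sp$end > hi)
    stop_slimscan(sprintf("span (%d,%d) out of bounds for record '%s' (%d-%d)",
                          sp$start, sp$end, record$id, lo, hi),
                  "slimscan_bounds_error")
  idx <- (sp$start - lo + 1L):(sp$end - lo + 1L)
  seq_record(record$id, record$residues[idx], offset = sp$start)
}

#' Locate a unique residue within a span
#'
#' Finds the single position inside `sp` whose residue equals `letter`,
#' e.g. the unique tryptophan of a tail.  Fails if the letter occurs zero
#' times or more than once within the span.
#'
#' @param record a [seq_record()].
#' @param sp a [span()] restricting the search (global coordinates).
#' @param letter one-letter amino-acid code; `X` is rejected.
#' @return The 1-based global index of the match.
#' @examples
#' fa <- parse_fasta(slimscan_fasta())
#' locate_unique_residue(fa$BmGtsf1L, span(63, 101), "W")  # 99
#' @export
locate_unique_residue <- function(record, sp, letter) {
  letter <- toupper(letter)
  if (identical(letter, "X"))
    stop_slimscan("cannot search for unknown residue 'X'", "slimscan_not_found_error")
  if (!letter %in% AA_ALPHABET)
    stop_slimscan(sprintf("'%s' is not an amino-acid code", letter),
                  "slimscan_not_found_error")
  sub <- subsequence(record, sp)
  hits <- which(sub$residues == letter)
  if (!length(hits))
    stop_slimscan(sprintf("no '%s' in %s[%d-%d]", letter, record$id,
                          sp$start, sp$end),
                  "slimscan_not_found_error")
  if (length(hits) > 1L)
    stop_slimscan(sprintf("ambiguous '%s' in %s[%d-%d]: positions %s",
                          letter, record$id, sp$start, sp$end,
                          paste(hits + sub$offset - 1L, collapse = ", ")),
                  "slimscan_ambiguity_error")
  hits + sub$offset - 1L
}
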