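# Fragment tiling of the disordered tail and the prediction-run manifest.
#
# The tail is tiled from up to three anchors (start, middle, end) with
# fragments of increasing nominal length: init_len, init_len + step, ...
# The series stops at the first nominal length that reaches or exceeds the
# tail length; that last fragment is clipped to the full tail.  With the
# worked configuration (tail of 39 aa, init 5, step 5, three anchors) this
# yields 24 fragments and, against three bait domains, 72 prediction runs.

ANCHORS <- c("start", "middle", "end")

#' Configure a fragment scan
#'
#' @param tail_span [span()] of the disordered tail in prey-sequence
#'   (global) coordinates.
#' @param init_len length of the first fragment per anchor (residues).
#' @param step length increment per extension step (residues).
#' @param anchors ordered subset of `c("start", "middle", "end")`.
#' @return Object of class `scan_config`.
#' @examples
#' scan_config(span(63, 101))   # the worked tail configuration
#' @export
scan_config <- function(tail_span, init_len = 5L, step = 5L,
                        anchors = c("start", "middle", "end")) {
  tail_span <- as_span(tail_span)
  init_len <- as.integer(init_len); step <- as.integer(step)
  if (init_len < 1L || step < 1L)
    stop_slimscan("init_len and step must be >= 1", "slimscan_config_error")
  if (!length(anchors) || !all(anchors %in% ANCHORS) || anyDuplicated(anchors))
    stop_slimscan("anchors must be a non-empty subset of start/middle/end",
                  "slimscan_config_error")
  if (span_length(tail_span) < init_len)
    stop_slimscan(sprintf("tail length %d shorter than init_len %d",
                          span_length(tail_span), init_len),
                  "slimscan_config_error")
  structure(list(tail_span = tail_span, init_len = init_len, step = step,
                 anchors = anchors),
            class = "scan_config")
}

# tail-local span of one fragment; shifts (never shortens) middle-anchored
# fragments that collide with the tail boundary
anchor_span <- function(anchor, len, L) {
  if (len >= L) return(c(1L, L))
  switch(anchor,
         start = c(1L, len),
         end = c(L - len + 1L, L),
         middle = {
           ctr <- as.integer(ceiling(L / 2))
           s <- ctr - as.integer(floor(len / 2))
           if (s < 1L) s <- 1L
           if (s + len - 1L > L) s <- L - len + 1L
           c(s, s + len - 1L)
         })
}

#' Enumerate tiled tail fragments
#'
#' For each anchor the nominal length series is `init_len, init_len+step,
#' ...`, stopping at the first length that reaches or exceeds the tail
#' length; that final fragment is clipped to the whole tail.  Middle
#' fragments are centred on `ceiling(L/2)` with a left-biased half-width
#' and shifted minimally to fit the tail without shortening.  Fragments
#' are kept per (anchor, nominal length) even when their spans coincide
#' across anchors: structure prediction is stochastic, so coincident
#' spans are informative replicates.
#'
#' @param config a [scan_config()].
#' @return data.frame of class `fragment_set`: `fragment_id`, `anchor`,
#'   `nominal_len`, `frag_start`/`frag_end` (tail-local), and
#'   `global_start`/`global_end` (prey-sequence coordinates).
#' @examples
#' nrow(enumerate_fragments(scan_config(span(63, 101))))  # 24
#' @export
enumerate_fragments <- function(config) {
  stopifnot(inherits(config, "scan_config"))
  L <- span_length(config$tail_span)
  lens <- config$init_len
  while (lens[length(lens)] < L) lens <- c(lens, lens[length(lens)] + config$step)
  rows <- list()
  for (anchor in config$anchors) {
    for (len in lens) {
      sp <- anchor_span(anchor, min(len, L), L)
      rows[[length(rows) + 1L]] <- data.frame(
        fragment_id = sprintf("%s:%d", anchor, len),
        anchor = anchor, nominal_len = as.integer(len),
        frag_start = sp[1], frag_end = sp[2],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  off <- config$tail_span$start - 1L
  out$global_start <- out$frag_start + off
  out$global_end <- out$frag_end + off
  class(out) <- c("fragment_set", "data.frame")
  out
}

#' Build the prediction-run manifest
#'
#' Pairs every fragment with every named bait domain (Cartesian product)
#' in a deterministic order: bait-domain order, then anchor order, then
#' increasing nominal length.  `run_id` encodes the bait domain and the
#' fragment.
#'
#' @param fragments a `fragment_set` from [enumerate_fragments()].
#' @param bait_domains named list of [span()]s on the bait sequence
#'   (e.g. the three extended Tudor domains).
#' @return data.frame of class `run_manifest` with one row per run:
#'   `run_id`, `bait_name`, `bait_start`, `bait_end`, plus all fragment
#'   columns.
#' @examples
#' frags <- enumerate_fragments(scan_config(span(63, 101)))
#' doms <- list(eTD0 = span(300, 420), eTD1 = span(700, 820),
#'              eTD2 = span(900, 1020))
#' nrow(build_manifest(frags, doms))  # 72
#' @export
build_manifest <- function(fragments, bait_domains) {
  if (!nrow(fragments))
    stop_slimscan("no fragments", "slimscan_config_error")
  if (!length(bait_domains) || is.null(names(bait_domains)) ||
      any(!nzchar(names(bait_domains))))
    stop_slimscan("bait_domains must be a named list of spans",
                  "slimscan_config_error")
  if (anyDuplicated(names(bait_domains)))
    stop_slimscan("duplicate bait-domain names", "slimscan_config_error")
  rows <- list()
  for (bn in names(bait_domains)) {
    dom <- as_span(bait_domains[[bn]])
    blk <- fragments
    blk$bait_name <- bn
    blk$bait_start <- dom$start
    blk$bait_end <- dom$end
    rows[[bn]] <- blk
  }
  out <- do.call(rbind, rows)
  out$run_id <- sprintf("%s_%s_%03d", out$bait_name, out$anchor, out$nominal_len)
  rownames(out) <- NULL
  out <- out[, c("run_id", "bait_name", "bait_start", "bait_end", "fragment_id",
                 "anchor", "nominal_len", "frag_start", "frag_end",
                 "global_start", "global_end")]
  class(out) <- c("run_manifest", "data.frame")
  out
}

#' Write / read a run manifest as TSV
#'
#' @param manifest a `run_manifest`.
#' @param path TSV file path.
#' @param provenance optional named list echoed as `# key: value` header
#'   lines.
#' @return `path` (write) or the manifest (read).
#' @export
write_manifest <- function(manifest, path, provenance = NULL) {
  write_tsv_prov(as.data.frame(manifest), path, provenance)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  out <- read_tsv_prov(path)
  class(out) <- c("run_manifest", "data.frame")
  out
}
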