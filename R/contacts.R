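# Inter-chain residue contact extraction.
#
# The model-contact rule: two residues, one per chain, are in contact if
# at least one heavy atom of one is less than 5 A from any heavy atom of
# the other (strict <).  The MD rule reuses the same engine with an
# inclusive <= at 4.5 A.

new_contact_set <- function(df, frame, cutoff, inclusive, heavy_only) {
  df <- df[order(df$bait_idx, df$prey_idx), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("contact_set", "data.frame"),
            frame = frame, cutoff = cutoff, inclusive = inclusive,
            heavy_only = heavy_only)
}

#' @export
print.contact_set <- function(x, ...) {
  cat(sprintf("<contact_set: %d pairs, %s frame, cutoff %g A (%s), %s>\n",
              nrow(x), attr(x, "frame"), attr(x, "cutoff"),
              if (attr(x, "inclusive")) "inclusive" else "strict",
              if (attr(x, "heavy_only")) "heavy atoms" else "all atoms"))
  if (nrow(x)) print.data.frame(utils::head(x, 10))
  invisible(x)
}

# atoms: data.frame with role/resno/hydrogen/x/y/z -> per-residue-pair
# minimum inter-chain atom distance, pairs passing the cutoff rule
min_dist_pairs <- function(atoms, cutoff, inclusive, heavy_only) {
  if (heavy_only) atoms <- atoms[!atoms$hydrogen, , drop = FALSE]
  b <- atoms[atoms$role == "bait", , drop = FALSE]
  p <- atoms[atoms$role == "prey", , drop = FALSE]
  if (!nrow(b) || !nrow(p))
    return(data.frame(bait_idx = integer(), prey_idx = integer(),
                      min_dist = numeric()))
  bx <- as.matrix(b[, c("x", "y", "z")])
  px <- as.matrix(p[, c("x", "y", "z")])
  d2 <- outer(rowSums(bx^2), rowSums(px^2), "+") - 2 * tcrossprod(bx, px)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  hit <- if (inclusive) d <= cutoff else d < cutoff
  idx <- which(hit, arr.ind = TRUE)
  if (!nrow(idx))
    return(data.frame(bait_idx = integer(), prey_idx = integer(),
                      min_dist = numeric()))
  df <- data.frame(bait_idx = b$resno[idx[, 1]], prey_idx = p$resno[idx[, 2]],
                   dist = d[idx])
  agg <- stats::aggregate(dist ~ bait_idx + prey_idx, data = df, FUN = min)
  data.frame(bait_idx = as.integer(agg$bait_idx),
             prey_idx = as.integer(agg$prey_idx),
             min_dist = agg$dist)
}

#' Extract inter-chain residue contacts from a structure model
#'
#' A bait/prey residue pair is in contact when the minimum distance over
#' one-atom-per-chain pairs passes the cutoff: strictly below it by
#' default (the predicted-model rule), or inclusively when
#' `inclusive = TRUE` (the trajectory rule).  Hydrogens and deuteriums
#' are excluded when `heavy_only = TRUE`.
#'
#' @param model a [load_structure()] model.
#' @param cutoff distance cutoff in Angstrom (default 5).
#' @param heavy_only exclude hydrogens (default `TRUE`).
#' @param inclusive use `<=` instead of strict `<` (default `FALSE`).
#' @return A `contact_set` data.frame (`bait_idx`, `prey_idx`,
#'   `min_dist`) in the `fragment_local` frame, with the rule recorded in
#'   attributes.
#' @export
interchain_contacts <- function(model, cutoff = 5, heavy_only = TRUE,
                                inclusive = FALSE) {
  stopifnot(inherits(model, "structure_model"))
  if (!is.numeric(cutoff) || cutoff <= 0)
    stop_slimscan("cutoff must be > 0", "slimscan_config_error")
  df <- min_dist_pairs(model$atoms, cutoff, inclusive, heavy_only)
  new_contact_set(df, "fragment_local", cutoff, inclusive, heavy_only)
}

#' Remap fragment-local contacts to global residue coordinates
#'
#' Models of a fragment run number prey residues 1..fragment length and
#' bait residues 1..domain length.  Overlaying runs requires the shared
#' global numbering: prey local `j` maps to `global_start + j - 1` of the
#' fragment, bait local `i` to `bait_start + i - 1` of the domain.
#'
#' @param contacts a `fragment_local` contact set.
#' @param fragment one row of a `run_manifest` (or any list with
#'   `global_start`, `global_end`).
#' @param bait_domain a [span()] of the bait domain, or `NULL` to take
#'   `bait_start`/`bait_end` from `fragment`.
#' @return The contact set in the `global` frame.
#' @export
remap_contacts <- function(contacts, fragment, bait_domain = NULL) {
  stopifnot(inherits(contacts, "contact_set"))
  if (!identical(attr(contacts, "frame"), "fragment_local"))
    stop_slimscan("contacts are not in the fragment_local frame",
                  "slimscan_mapping_error")
  if (is.null(bait_domain))
    bait_domain <- span(fragment$bait_start, fragment$bait_end)
  bait_domain <- as_span(bait_domain)
  frag_len <- fragment$global_end - fragment$global_start + 1L
  dom_len <- span_length(bait_domain)
  if (nrow(contacts)) {
    if (any(contacts$prey_idx < 1L | contacts$prey_idx > frag_len))
      stop_slimscan("prey contact index exceeds fragment length",
                    "slimscan_mapping_error")
    if (any(contacts$bait_idx < 1L | contacts$bait_idx > dom_len))
      stop_slimscan("bait contact index exceeds bait-domain length",
                    "slimscan_mapping_error")
  }
  df <- as.data.frame(contacts)
  df$prey_idx <- df$prey_idx + fragment$global_start - 1L
  df$bait_idx <- df$bait_idx + bait_domain$start - 1L
  new_contact_set(df, "global", attr(contacts, "cutoff"),
                  attr(contacts, "inclusive"), attr(contacts, "heavy_only"))
}

#' Write a per-run contact list as TSV
#'
#' @param contacts a `contact_set`.
#' @param path output TSV.
#' @param run_id run identifier recorded in the first column.
#' @param provenance optional named list echoed as header comments.
#' @return `path`, invisibly.
#' @export
write_contacts <- function(contacts, path, run_id = NA_character_,
                           provenance = NULL) {
  df <- as.data.frame(contacts)
  df <- cbind(run_id = run_id, df)
  write_tsv_prov(df, path, provenance)
}
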