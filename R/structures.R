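# Two-chain structure models: PDB loading, run-directory metadata, and
# top-ranked model selection.

# Infer element symbols from the PDB element column, falling back to
# atom-name heuristics (predicted models frequently omit the element
# column).  Hydrogen/deuterium are what the heavy-atom rule excludes.
# deliberately excludes CA/CD/NA, which in protein atom names are the
# alpha/delta carbons and backbone nitrogen, not calcium/cadmium/sodium
TWO_LETTER_ELEMENTS <- c("FE", "ZN", "MG", "MN", "CU", "NI", "CO",
                         "CL", "BR", "SE")

infer_element <- function(elety, elesy = NULL) {
  ele <- toupper(trimws(elesy %||% rep("", length(elety))))
  ele[is.na(ele)] <- ""
  miss <- !nzchar(ele)
  if (any(miss)) {
    nm <- toupper(gsub("[^A-Za-z]", "", elety[miss]))
    guess <- substr(nm, 1L, 1L)
    two <- substr(nm, 1L, 2L) %in% TWO_LETTER_ELEMENTS & nchar(nm) == nchar(elety[miss])
    guess[two] <- substr(nm[two], 1L, 2L)
    # names like 1HB2 / HG21: leading digit already stripped; H first wins
    ele[miss] <- guess
  }
  ele
}

#' Construct a two-chain structure model from an atom table
#'
#' Programmatic constructor used by the synthetic-data generators and in
#' tests; [load_structure()] is the file-based entry point.
#'
#' @param atoms data.frame with columns `role` (`"bait"`/`"prey"`),
#'   `chain`, `resno`, `resid`, `elety`, `x`, `y`, `z`; `element` and
#'   `hydrogen` are inferred when absent.
#' @param bait_chain,prey_chain chain identifiers.
#' @param source provenance label.
#' @return A `structure_model`.
#' @export
structure_model <- function(atoms, bait_chain = "A", prey_chain = "B",
                            source = "constructed") {
  if (is.null(atoms$element)) atoms$element <- infer_element(atoms$elety)
  if (is.null(atoms$hydrogen)) atoms$hydrogen <- atoms$element %in% c("H", "D")
  if (!nrow(atoms) || any(!is.finite(atoms$x + atoms$y + atoms$z)))
    stop_slimscan("atom table empty or with non-finite coordinates",
                  "slimscan_format_error")
  atoms$resno <- as.integer(atoms$resno)
  structure(list(atoms = atoms, bait_chain = bait_chain,
                 prey_chain = prey_chain, source = source),
            class = "structure_model")
}

#' Write a structure model as PDB
#'
#' @param model a `structure_model`.
#' @param path output PDB file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  at <- model$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(as.matrix(at[, c("x", "y", "z")]))),
                   resno = at$resno, chain = at$chain, resid = at$resid,
                   elety = at$elety)
  invisible(path)
}

#' Load a two-chain structure model from a PDB file
#'
#' Retains exactly the two named chains (any others are dropped with a
#' warning), preserves residue order, and infers element symbols.
#' Hydrogens are kept in storage but flagged, so the heavy-atom contact
#' rule can exclude them.  Alternate locations other than the first are
#' discarded.
#'
#' @param path PDB file.
#' @param bait_chain,prey_chain chain identifiers of the bait domain and
#'   the prey fragment.
#' @return Object of class `structure_model`: `atoms` (data.frame with
#'   `role`, `chain`, `resno`, `resid`, `elety`, `element`, `hydrogen`,
#'   `x`, `y`, `z`), `bait_chain`, `prey_chain`, `source`.
#' @export
load_structure <- function(path, bait_chain = "A", prey_chain = "B") {
  if (!file.exists(path))
    stop_slimscan(sprintf("PDB file not found: %s", path), "slimscan_format_error")
  pdb <- tryCatch(bio3d::read.pdb(path, rm.alt = TRUE, verbose = FALSE),
                  error = function(e)
                    stop_slimscan(sprintf("cannot parse PDB %s: %s", path,
                                          conditionMessage(e)),
                                  "slimscan_format_error"))
  at <- pdb$atom[pdb$atom$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  if (!nrow(at))
    stop_slimscan(sprintf("%s: no atoms", path), "slimscan_format_error")
  chains <- unique(at$chain)
  for (ch in c(bait_chain, prey_chain))
    if (!ch %in% chains)
      stop_slimscan(sprintf("%s: chain '%s' not present (found: %s)", path, ch,
                            paste(chains, collapse = ",")),
                    "slimscan_format_error")
  extra <- setdiff(chains, c(bait_chain, prey_chain))
  if (length(extra))
    warning(sprintf("%s: dropping chain(s) %s", path,
                    paste(extra, collapse = ",")), call. = FALSE)
  at <- at[at$chain %in% c(bait_chain, prey_chain), , drop = FALSE]
  if (any(!is.finite(at$x)) || any(!is.finite(at$y)) || any(!is.finite(at$z)))
    stop_slimscan(sprintf("%s: non-finite coordinates", path),
                  "slimscan_format_error")
  element <- infer_element(at$elety, at$elesy)
  atoms <- data.frame(
    role = ifelse(at$chain == bait_chain, "bait", "prey"),
    chain = at$chain, resno = as.integer(at$resno), resid = at$resid,
    elety = at$elety, element = element,
    hydrogen = element %in% c("H", "D"),
    x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE)
  structure(list(atoms = atoms, bait_chain = bait_chain,
                 prey_chain = prey_chain, source = path),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  nb <- length(unique(x$atoms$resno[x$atoms$role == "bait"]))
  np <- length(unique(x$atoms$resno[x$atoms$role == "prey"]))
  cat(sprintf("<structure_model: bait chain %s (%d res), prey chain %s (%d res), %d atoms>\n",
              x$bait_chain, nb, x$prey_chain, np, nrow(x$atoms)))
  invisible(x)
}

#' Select the top-ranked model of a prediction run
#'
#' Prediction engines emit several models per run plus a ranking; only the
#' first-ranked model is used downstream.  Two metadata dialects are
#' understood: the package-native `metadata.json` (`ranking` lists model
#' basenames best-first, the first entry naming `<name>.pdb`), and the
#' AlphaFold `ranking_debug.json` layout, where the top model is the file
#' `ranked_0.pdb` by construction.
#'
#' @param run_dir a prediction-run directory.
#' @return Path of the top-ranked model file.
#' @export
select_top_model <- function(run_dir) {
  meta <- load_run_metadata(run_dir)
  top <- meta$ranking[1]
  cand <- file.path(run_dir, paste0(top, ".pdb"))
  if (!file.exists(cand))
    stop_slimscan(sprintf("run %s: top-ranked model file missing: %s",
                          meta$run_id, cand),
                  "slimscan_run_error")
  cand
}

#' Load prediction-run metadata
#'
#' Reads the ranking, the scalar model confidence and, when present, the
#' PAE (predicted aligned error) matrix.  The native dialect is a
#' `metadata.json` with fields `run_id`, `ranking`, `confidence` and
#' optionally `pae`; alternatively an AlphaFold-style
#' `ranking_debug.json` (`order` plus a score map) is accepted, with the
#' PAE read from `pae.json` (`predicted_aligned_error`) if present.
#'
#' @param run_dir a prediction-run directory.
#' @return Object of class `run_metadata`: `run_id`, `ranking`
#'   (best-first model names), `confidence` in `[0,1]`, `pae` (matrix or
#'   `NULL`).
#' @export
load_run_metadata <- function(run_dir) {
  native <- file.path(run_dir, "metadata.json")
  afjson <- file.path(run_dir, "ranking_debug.json")
  if (file.exists(native)) {
    m <- jsonlite::read_json(native, simplifyVector = TRUE)
    run_id <- m$run_id %||% basename(run_dir)
    ranking <- as.character(m$ranking)
    confidence <- as.numeric(m$confidence)
    pae <- if (!is.null(m$pae)) as.matrix(m$pae) else NULL
  } else if (file.exists(afjson)) {
    m <- jsonlite::read_json(afjson, simplifyVector = TRUE)
    run_id <- basename(run_dir)
    ord <- as.character(m$order)
    scores <- m[["iptm+ptm"]] %||% m$plddts
    confidence <- as.numeric(scores[[ord[1]]])
    # AlphaFold writes models renamed by rank; ranked_0 is the top model
    ranking <- paste0("ranked_", seq_along(ord) - 1L)
    paefile <- file.path(run_dir, "pae.json")
    pae <- if (file.exists(paefile)) {
      pj <- jsonlite::read_json(paefile, simplifyVector = TRUE)
      as.matrix(pj$predicted_aligned_error %||% pj)
    } else NULL
  } else {
    stop_slimscan(sprintf("run %s: no metadata.json or ranking_debug.json",
                          basename(run_dir)),
                  "slimscan_run_error")
  }
  if (!length(ranking))
    stop_slimscan(sprintf("run %s: empty model ranking", run_id),
                  "slimscan_run_error")
  if (!is.finite(confidence) || confidence < 0 || confidence > 1)
    stop_slimscan(sprintf("run %s: model confidence %s outside [0,1]",
                          run_id, format(confidence)),
                  "slimscan_validation_error")
  if (!is.null(pae)) {
    if (nrow(pae) != ncol(pae))
      stop_slimscan(sprintf("run %s: PAE matrix not square", run_id),
                    "slimscan_validation_error")
  }
  structure(list(run_id = run_id, ranking = ranking,
                 confidence = confidence, pae = pae),
            class = "run_metadata")
}
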