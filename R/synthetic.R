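# Synthetic fixtures with planted interfaces.
#
# Residues are realised as 1-4 pseudo-atoms; no physical geometry is
# attempted, because every downstream statistic depends only on
# interatomic distances.  Planted bait/prey pairs are realised at
# exactly `contact_distance`; all other inter-chain pairs sit at or
# beyond `background_min_distance`, so any cutoff between the two
# recovers exactly the planted pairs.  All generators are reproducible
# from (spec, seed).

#' Specify a toy two-chain complex
#'
#' @param bait_length,prey_length residue counts of the two chains.
#' @param planted_pairs data.frame (or 2-column matrix) of
#'   `bait_idx`/`prey_idx` pairs to realise in contact; chain-local
#'   1-based indices.
#' @param contact_distance closest-atom distance of planted pairs in
#'   Angstrom (default 4).
#' @param background_min_distance minimum distance of all other
#'   inter-chain pairs (default 8).
#' @param noise_rate probability that an off-pair is spuriously planted
#'   as a contact (independent Bernoulli per pair; default 0).
#' @param seed RNG seed for noise sampling.
#' @return Object of class `toy_complex_spec`.
#' @export
toy_complex_spec <- function(bait_length, prey_length,
                             planted_pairs = NULL, contact_distance = 4,
                             background_min_distance = 8, noise_rate = 0,
                             seed = 1L) {
  pp <- if (is.null(planted_pairs) || !NROW(planted_pairs)) {
    data.frame(bait_idx = integer(), prey_idx = integer())
  } else {
    pp <- as.data.frame(planted_pairs)
    names(pp)[1:2] <- c("bait_idx", "prey_idx")
    pp$bait_idx <- as.integer(pp$bait_idx); pp$prey_idx <- as.integer(pp$prey_idx)
    pp
  }
  if (nrow(pp) && (any(pp$bait_idx < 1L | pp$bait_idx > bait_length) ||
                   any(pp$prey_idx < 1L | pp$prey_idx > prey_length)))
    stop_slimscan("planted pair indices outside chain lengths",
                  "slimscan_construction_error")
  if (contact_distance >= background_min_distance)
    stop_slimscan("contact_distance must be below background_min_distance",
                  "slimscan_construction_error")
  structure(list(bait_length = as.integer(bait_length),
                 prey_length = as.integer(prey_length),
                 planted_pairs = pp,
                 contact_distance = contact_distance,
                 background_min_distance = background_min_distance,
                 noise_rate = noise_rate, seed = as.integer(seed)),
            class = "toy_complex_spec")
}

# realise a pair list as atoms; used by both the complex and trajectory
# generators.  Bait residue i: CA at (s*i, 0, 0), CB at (s*i, 0, -1.5).
# Prey residue j: CA at (s*j, Y, 0) with Y safely beyond background.
# Each planted pair (i, j) adds one prey pseudo-atom on the sphere of
# radius contact_distance around bait CA i, tilted upwards so the
# closest approach of the pair is exactly contact_distance.
toy_atoms <- function(spec, pairs) {
  s <- spec$background_min_distance + 2
  Y <- spec$background_min_distance + spec$contact_distance + 4
  cd <- spec$contact_distance
  per_prey <- table(factor(pairs$prey_idx, levels = seq_len(spec$prey_length)))
  if (any(per_prey > 3L))
    stop_slimscan(sprintf("prey residue %s in more than 3 planted pairs (max 4 pseudo-atoms per residue)",
                          names(per_prey)[which(per_prey > 3L)[1]]),
                  "slimscan_construction_error")
  bait <- data.frame(
    role = "bait", chain = "A",
    resno = rep(seq_len(spec$bait_length), each = 2L), resid = "ALA",
    elety = rep(c("CA", "CB"), spec$bait_length),
    x = rep(s * seq_len(spec$bait_length), each = 2L),
    y = 0, z = rep(c(0, -1.5), spec$bait_length),
    stringsAsFactors = FALSE)
  prey <- data.frame(
    role = "prey", chain = "B", resno = seq_len(spec$prey_length),
    resid = "ALA", elety = "CA",
    x = s * seq_len(spec$prey_length), y = Y, z = 0,
    stringsAsFactors = FALSE)
  if (nrow(pairs)) {
    pairs <- pairs[order(pairs$prey_idx, pairs$bait_idx), , drop = FALSE]
    contact_names <- c("CB", "CG", "CD")
    k_per_bait <- integer(spec$bait_length)   # tilt index per bait residue
    k_per_prey <- integer(spec$prey_length)   # atom name index per prey residue
    extra <- vector("list", nrow(pairs))
    for (r in seq_len(nrow(pairs))) {
      i <- pairs$bait_idx[r]; j <- pairs$prey_idx[r]
      k_per_bait[i] <- k_per_bait[i] + 1L
      k_per_prey[j] <- k_per_prey[j] + 1L
      theta <- (k_per_bait[i] - 1L) * 10 * pi / 180  # tilt away from bait CB
      extra[[r]] <- data.frame(
        role = "prey", chain = "B", resno = j, resid = "ALA",
        elety = contact_names[k_per_prey[j]],
        x = s * i, y = cd * cos(theta), z = cd * sin(theta),
        stringsAsFactors = FALSE)
    }
    prey <- rbind(prey, do.call(rbind, extra))
    prey <- prey[order(prey$resno), , drop = FALSE]
  }
  out <- rbind(bait, prey)
  rownames(out) <- NULL
  out
}

# planted pairs plus Bernoulli(noise_rate) off-pairs, capped at 3
# contact atoms per prey residue; draws from the current RNG stream
sample_pairs <- function(spec) {
  pairs <- spec$planted_pairs
  if (spec$noise_rate > 0) {
    all <- expand.grid(bait_idx = seq_len(spec$bait_length),
                       prey_idx = seq_len(spec$prey_length))
    key <- paste(all$bait_idx, all$prey_idx)
    off <- all[!key %in% paste(pairs$bait_idx, pairs$prey_idx), , drop = FALSE]
    off <- off[order(off$bait_idx, off$prey_idx), , drop = FALSE]
    flip <- stats::runif(nrow(off)) < spec$noise_rate
    noise <- off[flip, , drop = FALSE]
    if (nrow(noise)) {
      load <- table(factor(pairs$prey_idx, levels = seq_len(spec$prey_length)))
      keep <- logical(nrow(noise))
      for (r in seq_len(nrow(noise))) {
        j <- noise$prey_idx[r]
        if (load[j] < 3L) { keep[r] <- TRUE; load[j] <- load[j] + 1L }
      }
      pairs <- rbind(pairs, noise[keep, , drop = FALSE])
    }
  }
  pairs
}

#' Generate a toy two-chain complex with planted contacts
#'
#' @param spec a [toy_complex_spec()].
#' @param path optional PDB output path; when given the model is also
#'   written to disk.
#' @return A `structure_model` whose inter-chain contact set, at any
#'   cutoff between `contact_distance` and `background_min_distance`,
#'   is exactly the planted (plus sampled noise) pairs.
#' @export
make_toy_complex <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "toy_complex_spec"))
  set.seed(spec$seed)
  pairs <- sample_pairs(spec)
  model <- structure_model(toy_atoms(spec, pairs), source = "toy_complex")
  attr(model, "realized_pairs") <- pairs
  if (!is.null(path)) {
    write_structure(model, path)
    model$source <- path
  }
  model
}

#' Generate a mock prediction-run directory tree for a fragment scan
#'
#' Stands in for an ensemble of structure-prediction runs.  Each
#' manifest entry becomes one run directory containing model PDBs and a
#' `metadata.json`.  Runs of the pocket-bearing bait domain whose
#' fragment covers the motif get planted motif-to-pocket contacts in
#' their top-ranked model; every off-pair flips to a spurious contact
#' independently with probability `noise_rate`.  Decoy models carry no
#' planted interface, and the ranking permutes model names so that the
#' top model is not the lexicographically first file.  Confidences are
#' drawn higher for motif-covering runs than for the rest, mirroring the
#' contrast real prediction ensembles show between specific and
#' non-specific pairings.
#'
#' @param manifest a `run_manifest` from [build_manifest()].
#' @param motif_span [span()] of the planted motif in prey-global
#'   coordinates.
#' @param pocket_span [span()] of the pocket residues on the bait; must
#'   lie within exactly one of the manifest's bait domains (at most 3
#'   residues, so every motif residue can pair with the full pocket).
#' @param out_dir directory to create run subdirectories in.
#' @param noise_rate per-off-pair contact noise probability (default 0).
#' @param conf_motif,conf_background confidence ranges (length-2) for
#'   motif-covering pocket-domain runs vs all others.
#' @param contact_distance,background_min_distance geometry of the toy
#'   models (see [toy_complex_spec()]).
#' @param n_decoys decoy models per run (default 2).
#' @param seed RNG seed; the whole tree is reproducible from it.
#' @return Invisibly, a data.frame with one row per run: `run_id`,
#'   `dir`, `covers_motif`, `confidence`.
#' @export
make_mock_scan <- function(manifest, motif_span, pocket_span, out_dir,
                           noise_rate = 0, conf_motif = c(0.75, 0.9),
                           conf_background = c(0.2, 0.5),
                           contact_distance = 4,
                           background_min_distance = 8,
                           n_decoys = 2L, seed = 1L) {
  stopifnot(inherits(manifest, "run_manifest"))
  motif_span <- as_span(motif_span); pocket_span <- as_span(pocket_span)
  doms <- unique(manifest[, c("bait_name", "bait_start", "bait_end")])
  carrier <- doms$bait_name[doms$bait_start <= pocket_span$start &
                              doms$bait_end >= pocket_span$end]
  if (length(carrier) != 1L)
    stop_slimscan("pocket_span must fall within exactly one bait domain",
                  "slimscan_construction_error")
  if (span_length(pocket_span) > 3L)
    stop_slimscan("pocket_span larger than 3 residues cannot be fully paired (max 4 pseudo-atoms per prey residue)",
                  "slimscan_construction_error")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  rows <- vector("list", nrow(manifest))
  for (r in seq_len(nrow(manifest))) {
    e <- as.list(manifest[r, ])
    dom_len <- e$bait_end - e$bait_start + 1L
    frag_len <- e$global_end - e$global_start + 1L
    mot_lo <- max(motif_span$start, e$global_start)
    mot_hi <- min(motif_span$end, e$global_end)
    covers <- e$bait_name == carrier && mot_lo <= mot_hi
    planted <- if (covers) {
      expand.grid(bait_idx = (pocket_span$start:pocket_span$end) - e$bait_start + 1L,
                  prey_idx = (mot_lo:mot_hi) - e$global_start + 1L)
    } else NULL
    cspec <- toy_complex_spec(dom_len, frag_len, planted,
                              contact_distance = contact_distance,
                              background_min_distance = background_min_distance,
                              noise_rate = noise_rate)
    run_dir <- file.path(out_dir, e$run_id)
    dir.create(run_dir, showWarnings = FALSE)
    # top model: planted pairs + noise; decoys: background only
    top_pairs <- sample_pairs(cspec)
    names_all <- sprintf("model_%d", seq_len(n_decoys + 1L))
    assign_order <- sample(names_all)        # permuted file naming
    top_name <- assign_order[1]
    write_structure(structure_model(toy_atoms(cspec, top_pairs),
                                    source = "mock_scan"),
                    file.path(run_dir, paste0(top_name, ".pdb")))
    empty <- cspec$planted_pairs[0, , drop = FALSE]
    for (dk in seq_len(n_decoys))
      write_structure(structure_model(toy_atoms(cspec, empty),
                                      source = "mock_scan"),
                      file.path(run_dir, paste0(assign_order[dk + 1L], ".pdb")))
    conf_range <- if (covers) conf_motif else conf_background
    confidence <- stats::runif(1, conf_range[1], conf_range[2])
    jsonlite::write_json(list(run_id = e$run_id, ranking = assign_order,
                              confidence = confidence),
                         file.path(run_dir, "metadata.json"),
                         auto_unbox = TRUE, digits = NA)
    rows[[r]] <- data.frame(run_id = e$run_id, dir = run_dir,
                            covers_motif = covers, confidence = confidence,
                            stringsAsFactors = FALSE)
  }
  invisible(do.call(rbind, rows))
}

#' Specify a toy trajectory
#'
#' @param complex_spec a [toy_complex_spec()] defining the bound-state
#'   geometry (its planted pairs are the bound interface).
#' @param n_frames number of frames.
#' @param bound_fraction fraction of frames in the bound geometry
#'   (default 1); the first `round(bound_fraction * n_frames)` frames
#'   are bound.
#' @param jitter_sigma per-coordinate Gaussian jitter SD in Angstrom
#'   (default 0).
#' @param unbinding_frame optional index of the last bound frame: frames
#'   up to it are bound, later frames unbound (overrides
#'   `bound_fraction`).
#' @param frame_spacing ns per frame (metadata only).
#' @param seed RNG seed (jitter).
#' @return Object of class `toy_trajectory_spec`.
#' @export
toy_trajectory_spec <- function(complex_spec, n_frames, bound_fraction = 1,
                                jitter_sigma = 0, unbinding_frame = NULL,
                                frame_spacing = 1, seed = 1L) {
  stopifnot(inherits(complex_spec, "toy_complex_spec"))
  if (n_frames < 1L)
    stop_slimscan("n_frames must be >= 1", "slimscan_construction_error")
  if (bound_fraction < 0 || bound_fraction > 1)
    stop_slimscan("bound_fraction must be in [0,1]", "slimscan_construction_error")
  structure(list(complex_spec = complex_spec, n_frames = as.integer(n_frames),
                 bound_fraction = bound_fraction, jitter_sigma = jitter_sigma,
                 unbinding_frame = unbinding_frame,
                 frame_spacing = frame_spacing, seed = as.integer(seed)),
            class = "toy_trajectory_spec")
}

#' Generate a toy trajectory with planted binding behaviour
#'
#' Bound frames use the toy-complex geometry; unbound frames translate
#' the prey chain away beyond the background separation, emulating a
#' motif leaving its pocket.  Seeded Gaussian jitter is added to every
#' coordinate of every frame.
#'
#' @param spec a [toy_trajectory_spec()].
#' @param path optional multi-model PDB output path.
#' @return A `trajectory`; the attribute `bound` records the planted
#'   per-frame bound state.
#' @export
make_toy_trajectory <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "toy_trajectory_spec"))
  cs <- spec$complex_spec
  set.seed(spec$seed)
  pairs <- sample_pairs(cs)
  atoms <- structure_model(toy_atoms(cs, pairs), source = "toy_trajectory")$atoms
  nf <- spec$n_frames
  bound <- if (!is.null(spec$unbinding_frame)) {
    seq_len(nf) <= spec$unbinding_frame
  } else {
    seq_len(nf) <= round(spec$bound_fraction * nf)
  }
  base <- as.matrix(atoms[, c("x", "y", "z")])
  shift <- cs$background_min_distance + 20
  prey_rows <- atoms$role == "prey"
  coords <- array(NA_real_, dim = c(nrow(atoms), 3L, nf))
  for (f in seq_len(nf)) {
    m <- base
    if (!bound[f]) m[prey_rows, 2] <- m[prey_rows, 2] + shift
    if (spec$jitter_sigma > 0)
      m <- m + matrix(stats::rnorm(length(m), sd = spec$jitter_sigma),
                      ncol = 3L)
    coords[, , f] <- m
  }
  traj <- new_trajectory(atoms, coords, spec$frame_spacing, "toy_trajectory")
  attr(traj, "bound") <- bound
  attr(traj, "realized_pairs") <- pairs
  if (!is.null(path)) write_trajectory(traj, path)
  traj
}
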