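# Trajectory contact maps, marginal interaction profiles, hydrogen-bond
# series and the motif-anchoring classification.
#
# The trajectory contact rule is inclusive: two residues are in contact
# in a frame if any pair of atoms (heavy atoms by default) is within
# 4.5 A.  Replicate maps started from the same structure are averaged
# elementwise into a single consensus map.

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT", "H", "HA", "H1", "H2", "H3")

#' Residue contacts of one trajectory frame
#'
#' @param traj a `trajectory`.
#' @param frame 1-based frame index.
#' @param cutoff distance cutoff in Angstrom (default 4.5, inclusive).
#' @param heavy_only exclude hydrogens (default `TRUE`; force-field
#'   trajectories carry hydrogens, set `FALSE` to count them).
#' @return A `contact_set` in the `global` frame (trajectory residue
#'   numbering is already global).
#' @export
frame_contacts <- function(traj, frame, cutoff = 4.5, heavy_only = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  at <- frame_atoms(traj, frame)
  df <- min_dist_pairs(at, cutoff, inclusive = TRUE, heavy_only = heavy_only)
  new_contact_set(df, "global", cutoff, TRUE, heavy_only)
}

new_contact_map <- function(bait_idx, prey_idx, freq, n_frames, n_replicates) {
  dimnames(freq) <- list(bait_idx, prey_idx)
  structure(list(bait_idx = bait_idx, prey_idx = prey_idx, freq = freq,
                 n_frames = n_frames, n_replicates = n_replicates),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map: %d bait x %d prey residues, %d frames, %d replicate(s)>\n",
              length(x$bait_idx), length(x$prey_idx), x$n_frames,
              x$n_replicates))
  invisible(x)
}

#' Per-pair contact frequency over a trajectory
#'
#' `freq[i, j]` is the fraction of frames in which bait residue `i` and
#' prey residue `j` are in contact under the inclusive distance rule.
#'
#' @inheritParams frame_contacts
#' @return A `contact_map` (rows = bait residues, columns = prey
#'   residues, `n_replicates = 1`).
#' @export
trajectory_contact_map <- function(traj, cutoff = 4.5, heavy_only = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  bait_idx <- sort(unique(traj$topology$resno[traj$topology$role == "bait"]))
  prey_idx <- sort(unique(traj$topology$resno[traj$topology$role == "prey"]))
  counts <- matrix(0L, length(bait_idx), length(prey_idx))
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    cs <- frame_contacts(traj, f, cutoff, heavy_only)
    if (nrow(cs))
      counts[cbind(match(cs$bait_idx, bait_idx), match(cs$prey_idx, prey_idx))] <-
        counts[cbind(match(cs$bait_idx, bait_idx), match(cs$prey_idx, prey_idx))] + 1L
  }
  new_contact_map(bait_idx, prey_idx, counts / nf, nf, 1L)
}

#' Average replicate contact maps
#'
#' Elementwise arithmetic mean of maps computed on identical axes, e.g.
#' replicate simulations started from the same structure.
#'
#' @param maps list of `contact_map`s with identical axes.
#' @return A `contact_map`; `n_replicates` is the summed replicate count
#'   and `n_frames` the summed frame count.
#' @export
average_maps <- function(maps) {
  if (!length(maps)) stop_slimscan("no maps to average", "slimscan_shape_error")
  ref <- maps[[1]]
  for (m in maps[-1])
    if (!identical(m$bait_idx, ref$bait_idx) ||
        !identical(m$prey_idx, ref$prey_idx))
      stop_slimscan("contact maps have mismatching residue axes",
                    "slimscan_shape_error")
  freq <- Reduce(`+`, lapply(maps, `[[`, "freq")) / length(maps)
  new_contact_map(ref$bait_idx, ref$prey_idx, freq,
                  sum(vapply(maps, `[[`, 0L, "n_frames")),
                  sum(vapply(maps, `[[`, 0L, "n_replicates")))
}

#' Marginal interaction profiles of a contact map
#'
#' The relative probability of each residue interacting with residues of
#' the partner chain: the sum of contact frequencies along the partner
#' axis.  Being sums of probabilities, values can exceed 1.
#'
#' @param map a `contact_map`.
#' @return List with `bait` and `prey` named numeric vectors.
#' @export
marginal_profiles <- function(map) {
  stopifnot(inherits(map, "contact_map"))
  list(bait = stats::setNames(rowSums(map$freq), map$bait_idx),
       prey = stats::setNames(colSums(map$freq), map$prey_idx))
}

#' Write a contact map as long-format TSV
#'
#' @param map a `contact_map`.
#' @param path output TSV.
#' @param provenance optional named list echoed as header comments.
#' @return `path`, invisibly.
#' @export
write_contact_map <- function(map, path, provenance = NULL) {
  df <- expand.grid(bait_idx = map$bait_idx, prey_idx = map$prey_idx)
  df$freq <- as.vector(map$freq)
  df <- df[order(df$bait_idx, df$prey_idx), ]
  write_tsv_prov(df, path, c(list(n_frames = map$n_frames,
                                  n_replicates = map$n_replicates),
                             provenance))
}

# locate one atom in a topology by chain role (or chain id), residue
# number and atom name; errors if absent or ambiguous
find_atom <- function(topology, resno, elety, role = NULL, chain = NULL) {
  sel <- topology$resno == resno & topology$elety == elety
  if (!is.null(role)) sel <- sel & topology$role == role
  if (!is.null(chain)) sel <- sel & topology$chain == chain
  hit <- which(sel)
  if (!length(hit))
    stop_slimscan(sprintf("atom %s of residue %d not found", elety, resno),
                  "slimscan_lookup_error")
  if (length(hit) > 1L)
    stop_slimscan(sprintf("atom %s of residue %d is ambiguous; give role or chain",
                          elety, resno),
                  "slimscan_lookup_error")
  hit
}

#' Hydrogen-bond geometry series along a trajectory
#'
#' Records the donor-acceptor distance in every frame and classifies the
#' bond as engaged when the distance is at most `dist_cutoff` and, if a
#' hydrogen atom is given, the donor-hydrogen-acceptor angle is at least
#' `angle_cutoff`.  Without a hydrogen (e.g. heavy-atom-only input) the
#' criterion is distance-only.
#'
#' @param traj a `trajectory`.
#' @param donor,acceptor,hydrogen atom selectors: lists with `resno`,
#'   `elety` and optionally `role` (`"bait"`/`"prey"`) or `chain`;
#'   `hydrogen = NULL` for the distance-only criterion.
#' @param dist_cutoff donor-acceptor distance cutoff in Angstrom
#'   (default 3.5).
#' @param angle_cutoff D-H-A angle cutoff in degrees (default 150).
#' @return Object of class `hbond_series`: `distance` (per frame, A),
#'   `angle` (per frame, degrees, or `NULL`), `engaged` (logical per
#'   frame), `persistence` (engaged fraction).
#' @export
hbond_series <- function(traj, donor, acceptor, hydrogen = NULL,
                         dist_cutoff = 3.5, angle_cutoff = 150) {
  stopifnot(inherits(traj, "trajectory"))
  pick <- function(sel) find_atom(traj$topology, sel$resno, sel$elety,
                                  sel$role %||% NULL, sel$chain %||% NULL)
  id <- pick(donor); ia <- pick(acceptor)
  ih <- if (!is.null(hydrogen)) pick(hydrogen) else NULL
  xyz <- function(i) matrix(traj$coords[i, , ], nrow = 3L)  # 3 x n_frames
  d <- xyz(id); a <- xyz(ia)
  dist <- sqrt(colSums((d - a)^2))
  angle <- NULL
  engaged <- dist <= dist_cutoff
  if (!is.null(ih)) {
    h <- xyz(ih)
    v1 <- d - h   # H -> D
    v2 <- a - h   # H -> A
    cosang <- colSums(v1 * v2) / (sqrt(colSums(v1^2)) * sqrt(colSums(v2^2)))
    cosang <- pmin(1, pmax(-1, cosang))
    angle <- acos(cosang) * 180 / pi
    engaged <- engaged & angle >= angle_cutoff
  }
  structure(list(donor = donor, hydrogen = hydrogen, acceptor = acceptor,
                 distance = as.numeric(dist), angle = angle,
                 engaged = engaged, persistence = mean(engaged),
                 dist_cutoff = dist_cutoff, angle_cutoff = angle_cutoff),
            class = "hbond_series")
}

#' @export
print.hbond_series <- function(x, ...) {
  cat(sprintf("<hbond_series: %d frames, persistence %.3f, mean D-A %.2f A>\n",
              length(x$distance), x$persistence, mean(x$distance)))
  invisible(x)
}

#' Classify motif anchoring across replicate trajectories
#'
#' A replicate is anchored when the motif residue's side-chain heavy
#' atoms stay within `cutoff` of any pocket-residue heavy atom for at
#' least `frame_fraction_threshold` of the frames.  This operationalises
#' the question of whether the anchor residue (e.g. the motif
#' tryptophan) remains in its binding pocket for the bulk of a
#' simulation.
#'
#' @param trajs a `trajectory` or list of replicate `trajectory`s.
#' @param motif_residue prey residue number of the anchor residue.
#' @param pocket_residues bait residue numbers forming the pocket.
#' @param cutoff contact distance in Angstrom (default 4.5, inclusive).
#' @param frame_fraction_threshold minimum in-pocket frame fraction for
#'   an anchored call (default 0.5).
#' @return Object of class `anchoring_result`: `in_pocket_fraction` and
#'   `anchored` per replicate, `n_anchored`, `n_replicates`.
#' @export
classify_anchored <- function(trajs, motif_residue, pocket_residues,
                              cutoff = 4.5, frame_fraction_threshold = 0.5) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  if (!(frame_fraction_threshold > 0 && frame_fraction_threshold <= 1))
    stop_slimscan("frame_fraction_threshold must be in (0,1]",
                  "slimscan_config_error")
  fracs <- vapply(trajs, function(traj) {
    top <- traj$topology
    mot <- which(top$role == "prey" & top$resno == motif_residue &
                   !top$hydrogen & !top$elety %in% BACKBONE_ATOMS)
    if (!length(mot))
      stop_slimscan(sprintf("motif residue %d has no side-chain heavy atoms",
                            motif_residue),
                    "slimscan_definition_error")
    poc <- which(top$role == "bait" & top$resno %in% pocket_residues &
                   !top$hydrogen)
    if (!length(poc))
      stop_slimscan("no pocket heavy atoms found", "slimscan_definition_error")
    hits <- vapply(seq_len(n_frames(traj)), function(f) {
      mm <- matrix(traj$coords[mot, , f], ncol = 3L)
      pp <- matrix(traj$coords[poc, , f], ncol = 3L)
      d2 <- outer(rowSums(mm^2), rowSums(pp^2), "+") - 2 * tcrossprod(mm, pp)
      sqrt(max(0, min(d2))) <= cutoff
    }, TRUE)
    mean(hits)
  }, 0)
  anchored <- fracs >= frame_fraction_threshold
  structure(list(in_pocket_fraction = fracs, anchored = anchored,
                 n_anchored = sum(anchored), n_replicates = length(trajs),
                 cutoff = cutoff,
                 frame_fraction_threshold = frame_fraction_threshold),
            class = "anchoring_result")
}

#' @export
print.anchoring_result <- function(x, ...) {
  cat(sprintf("<anchoring_result: %d of %d replicates anchored (threshold %.2f)>\n",
              x$n_anchored, x$n_replicates, x$frame_fraction_threshold))
  invisible(x)
}
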