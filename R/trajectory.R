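# Trajectories: a fixed two-chain topology plus per-frame coordinates.
# Core interchange format is multi-model PDB; a plain per-frame
# coordinate table keyed to a topology PDB is also accepted.

new_trajectory <- function(topology, coords, frame_spacing = NA_real_,
                           source = NA_character_) {
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  if (dim(coords)[1] != nrow(topology))
    stop_slimscan("frame atom count differs from topology",
                  "slimscan_format_error")
  if (dim(coords)[3] < 1L)
    stop_slimscan("trajectory needs at least one frame", "slimscan_format_error")
  structure(list(topology = topology, coords = coords,
                 frame_spacing = frame_spacing, source = source),
            class = "trajectory")
}

#' Number of frames in a trajectory
#' @param traj a `trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %d atoms, %d frames%s>\n", nrow(x$topology),
              n_frames(x),
              if (is.na(x$frame_spacing)) "" else
                sprintf(", %g ns/frame", x$frame_spacing)))
  invisible(x)
}

#' Read a multi-model PDB trajectory
#'
#' Each MODEL block is one frame; the first model supplies the two-chain
#' topology (per-atom chain, residue number, atom name, inferred
#' element).
#'
#' @param path multi-model PDB file.
#' @param bait_chain,prey_chain chain ids of the bait domain and prey
#'   peptide.
#' @param frame_spacing optional time per frame in ns (metadata only).
#' @return Object of class `trajectory`: `topology` (atom data.frame as
#'   in [load_structure()]), `coords` (atoms x 3 x frames array),
#'   `frame_spacing`.
#' @export
read_trajectory <- function(path, bait_chain = "A", prey_chain = "B",
                            frame_spacing = NA_real_) {
  model <- load_structure(path, bait_chain, prey_chain)
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = TRUE, verbose = FALSE)
  keep <- pdb$atom$chain %in% c(bait_chain, prey_chain) &
    pdb$atom$type %in% c("ATOM", "HETATM")
  xyz <- pdb$xyz[, bio3d::atom2xyz(which(keep)), drop = FALSE]
  nat <- sum(keep)
  nfr <- nrow(xyz)
  coords <- aperm(array(t(xyz), dim = c(3L, nat, nfr)), c(2L, 1L, 3L))
  new_trajectory(model$atoms, coords, frame_spacing, path)
}

#' Build a trajectory from a topology and a coordinate table
#'
#' Accepts per-frame coordinates as a long data.frame (`frame`, `atom`,
#' `x`, `y`, `z`; atoms in topology order within each frame).
#'
#' @param topology atom data.frame from [load_structure()] (`$atoms`).
#' @param table long-format coordinate data.frame.
#' @param frame_spacing optional ns per frame.
#' @return A `trajectory`.
#' @export
trajectory_from_table <- function(topology, table, frame_spacing = NA_real_) {
  frames <- sort(unique(table$frame))
  nat <- nrow(topology)
  coords <- array(NA_real_, dim = c(nat, 3L, length(frames)))
  for (k in seq_along(frames)) {
    blk <- table[table$frame == frames[k], , drop = FALSE]
    if (nrow(blk) != nat)
      stop_slimscan(sprintf("frame %s has %d atoms, topology has %d",
                            frames[k], nrow(blk), nat),
                    "slimscan_format_error")
    blk <- blk[order(blk$atom), , drop = FALSE]
    coords[, , k] <- as.matrix(blk[, c("x", "y", "z")])
  }
  new_trajectory(topology, coords, frame_spacing)
}

#' Write a trajectory as multi-model PDB
#'
#' @param traj a `trajectory`.
#' @param path output PDB file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  top <- traj$topology
  xyz <- t(apply(traj$coords, 3L, function(m) as.vector(t(m))))
  bio3d::write.pdb(file = path, xyz = xyz, resno = top$resno,
                   chain = top$chain, resid = top$resid, elety = top$elety)
  invisible(path)
}

# atom table of one frame (topology + that frame's coordinates)
frame_atoms <- function(traj, frame) {
  if (frame < 1L || frame > n_frames(traj))
    stop_slimscan(sprintf("frame %d out of range (1-%d)", frame, n_frames(traj)),
                  "slimscan_bounds_error")
  at <- traj$topology
  at$x <- traj$coords[, 1L, frame]
  at$y <- traj$coords[, 2L, frame]
  at$z <- traj$coords[, 3L, frame]
  at
}
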