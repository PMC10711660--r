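# Rigid-body least-squares (Kabsch) superposition and RMSD reporting.

#' Kabsch superposition of matched coordinate sets
#'
#' Finds the proper rotation (determinant +1; reflections are corrected
#' away, matching physical superposition) and translation minimising the
#' RMSD of `mobile` onto `target`, via singular value decomposition of
#' the cross-covariance of the centred sets.
#'
#' @param mobile,target numeric n x 3 matrices of matched coordinates,
#'   `n >= 3`, not all collinear.
#' @return Object of class `superposition`: `rotation` (3 x 3),
#'   `translation` (length 3; transformed = mobile %*% t(rotation) +
#'   translation), `rmsd` (A, after transform), `n_atoms`.
#' @examples
#' a <- matrix(rnorm(30), ncol = 3)
#' kabsch_superpose(a, a)$rmsd   # 0
#' @export
kabsch_superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (ncol(mobile) != 3L || ncol(target) != 3L)
    stop_slimscan("coordinate sets must be n x 3", "slimscan_geometry_error")
  if (nrow(mobile) != nrow(target))
    stop_slimscan("mobile and target have different atom counts",
                  "slimscan_geometry_error")
  if (nrow(mobile) < 3L)
    stop_slimscan("need at least 3 matched atoms", "slimscan_geometry_error")
  if (any(!is.finite(mobile)) || any(!is.finite(target)))
    stop_slimscan("non-finite coordinates", "slimscan_geometry_error")
  cm <- colMeans(mobile); ct <- colMeans(target)
  A <- sweep(mobile, 2L, cm); B <- sweep(target, 2L, ct)
  H <- crossprod(A, B)          # 3x3 cross-covariance
  sv <- svd(H)
  # collinear sets leave the rotation about the axis undetermined
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
    stop_slimscan("degenerate (collinear) coordinate set", "slimscan_geometry_error")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  moved <- A %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - B)^2)))
  translation <- ct - as.vector(R %*% cm)
  structure(list(rotation = R, translation = translation, rmsd = rmsd,
                 n_atoms = nrow(mobile)),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition: %d atoms, rmsd %.4f A>\n", x$n_atoms, x$rmsd))
  invisible(x)
}

#' Apply a superposition transform to coordinates
#'
#' @param coords n x 3 coordinate matrix.
#' @param sp a `superposition` from [kabsch_superpose()].
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(coords, sp) {
  stopifnot(inherits(sp, "superposition"))
  sweep(as.matrix(coords) %*% t(sp$rotation), 2L, sp$translation, "+")
}

#' Extract coordinates of selected residues from a structure model
#'
#' Convenience selector for range-based superposition; alpha-carbons by
#' default, with all-atom selection when atom names correspond
#' one-to-one between the structures being compared.
#'
#' @param model a `structure_model`.
#' @param ranges list of [span()]s of residue numbers.
#' @param role `"bait"` or `"prey"` chain.
#' @param elety atom name(s) to keep (default `"CA"`); `NULL` keeps all
#'   heavy atoms.
#' @return n x 3 coordinate matrix ordered by residue then atom.
#' @export
range_coords <- function(model, ranges, role = "bait", elety = "CA") {
  stopifnot(inherits(model, "structure_model"))
  at <- model$atoms[model$atoms$role == role & !model$atoms$hydrogen, ]
  keep <- rep(FALSE, nrow(at))
  for (r in ranges) {
    r <- as_span(r)
    keep <- keep | (at$resno >= r$start & at$resno <= r$end)
  }
  if (!is.null(elety)) keep <- keep & at$elety %in% elety
  at <- at[keep, , drop = FALSE]
  if (!nrow(at))
    stop_slimscan("no atoms selected for superposition", "slimscan_geometry_error")
  at <- at[order(at$resno), , drop = FALSE]
  as.matrix(at[, c("x", "y", "z")])
}

#' Superpose residue ranges of one model onto another
#'
#' Residue correspondences are supplied explicitly as paired range lists
#' (the ranges must select equal atom counts), e.g. aligning two
#' zinc-finger segments of a predicted model onto the matching segments
#' of an experimental structure.
#'
#' @param mobile,target `structure_model`s.
#' @param mobile_ranges,target_ranges lists of [span()]s (paired).
#' @param role chain to align on (default `"bait"`).
#' @param elety atom names used for matching (default `"CA"`).
#' @return A `superposition` (see [kabsch_superpose()]).
#' @export
superpose_ranges <- function(mobile, target, mobile_ranges, target_ranges,
                             role = "bait", elety = "CA") {
  kabsch_superpose(range_coords(mobile, mobile_ranges, role, elety),
                   range_coords(target, target_ranges, role, elety))
}
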