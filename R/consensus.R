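# Cross-run consensus: the contact-frequency matrix and its hotspots.
#
# For every bait/prey residue pair, freq = (number of runs in which the
# pair is in contact) / (number of runs whose fragment covers the prey
# residue).  Every run of a bait domain contains the full domain, so run
# coverage reduces to prey coverage; an all-runs denominator is offered
# for sensitivity analysis.

new_consensus_matrix <- function(bait_name, bait_idx, prey_idx, hits, denom,
                                 n_runs, denominator) {
  freq <- hits / denom
  freq[denom == 0] <- NA_real_
  structure(list(bait_name = bait_name, bait_idx = bait_idx,
                 prey_idx = prey_idx, hits = hits, denom = denom,
                 freq = freq, n_runs = n_runs, denominator = denominator),
            class = "consensus_matrix")
}

#' @export
print.consensus_matrix <- function(x, ...) {
  cat(sprintf("<consensus_matrix %s: %d bait x %d prey residues, %d runs, max freq %s>\n",
              x$bait_name, length(x$bait_idx), length(x$prey_idx), x$n_runs,
              if (all(is.na(x$freq))) "NA" else format(max(x$freq, na.rm = TRUE))))
  invisible(x)
}

#' Accumulate per-run contact sets into consensus matrices
#'
#' @param runs list of `list(entry = <one manifest row as list>, contacts
#'   = <global contact_set>)`; build entries with e.g.
#'   `as.list(manifest[i, ])`.
#' @param denominator `"covering"` (default; runs whose fragment contains
#'   the prey residue) or `"all"` (all runs of the bait domain).
#' @return Named list of `consensus_matrix` objects, one per bait domain,
#'   each holding `hits`, `denom` and `freq` matrices (rows = bait
#'   residues, columns = prey residues, global numbering).
#' @export
accumulate_runs <- function(runs, denominator = c("covering", "all")) {
  denominator <- match.arg(denominator)
  if (!length(runs))
    stop_slimscan("no runs to accumulate", "slimscan_consistency_error")
  entries <- lapply(runs, `[[`, "entry")
  baits <- vapply(entries, `[[`, "", "bait_name")
  out <- list()
  for (bn in unique(baits)) {
    sel <- which(baits == bn)
    es <- entries[sel]
    dom <- span(es[[1]]$bait_start, es[[1]]$bait_end)
    gstart <- vapply(es, function(e) as.integer(e$global_start), 0L)
    gend <- vapply(es, function(e) as.integer(e$global_end), 0L)
    bait_idx <- dom$start:dom$end
    prey_idx <- min(gstart):max(gend)
    hits <- matrix(0L, length(bait_idx), length(prey_idx),
                   dimnames = list(bait_idx, prey_idx))
    cover <- integer(length(prey_idx))
    for (k in seq_along(sel)) {
      e <- es[[k]]
      cs <- runs[[sel[k]]]$contacts
      if (!identical(attr(cs, "frame"), "global"))
        stop_slimscan(sprintf("run %s: contacts not in global frame", e$run_id),
                      "slimscan_consistency_error")
      cover <- cover + as.integer(prey_idx >= gstart[k] & prey_idx <= gend[k])
      if (nrow(cs)) {
        if (any(cs$prey_idx < gstart[k] | cs$prey_idx > gend[k]))
          stop_slimscan(sprintf("run %s: contact outside its fragment span",
                                e$run_id),
                        "slimscan_consistency_error")
        if (any(cs$bait_idx < dom$start | cs$bait_idx > dom$end))
          stop_slimscan(sprintf("run %s: contact outside its bait domain",
                                e$run_id),
                        "slimscan_consistency_error")
        ib <- match(cs$bait_idx, bait_idx)
        ip <- match(cs$prey_idx, prey_idx)
        hits[cbind(ib, ip)] <- hits[cbind(ib, ip)] + 1L
      }
    }
    denom_vec <- if (denominator == "covering") cover
                 else rep(length(sel), length(prey_idx))
    denom <- matrix(rep(denom_vec, each = length(bait_idx)),
                    nrow = length(bait_idx),
                    dimnames = dimnames(hits))
    out[[bn]] <- new_consensus_matrix(bn, bait_idx, prey_idx, hits, denom,
                                      length(sel), denominator)
  }
  out
}

#' Restrict a consensus matrix to residues observed in contact
#'
#' Drops bait rows and prey columns that were never in contact in any
#' run, mirroring how consensus heatmaps display only residues observed
#' at least once in contact with a partner residue.  Frequencies are
#' unchanged; the result may be empty.
#'
#' @param matrix a `consensus_matrix`.
#' @return A `consensus_matrix` on the restricted axes.
#' @export
observed_submatrix <- function(matrix) {
  stopifnot(inherits(matrix, "consensus_matrix"))
  keep_b <- rowSums(matrix$hits) > 0
  keep_p <- colSums(matrix$hits) > 0
  new_consensus_matrix(matrix$bait_name,
                       matrix$bait_idx[keep_b], matrix$prey_idx[keep_p],
                       matrix$hits[keep_b, keep_p, drop = FALSE],
                       matrix$denom[keep_b, keep_p, drop = FALSE],
                       matrix$n_runs, matrix$denominator)
}

# label 8-connected components of a logical matrix; 0 = background
label_components8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  nr <- nrow(mask); nc <- ncol(mask)
  for (i0 in seq_len(nr)) for (j0 in seq_len(nc)) {
    if (!mask[i0, j0] || lab[i0, j0] != 0L) next
    cur <- cur + 1L
    queue <- list(c(i0, j0))
    lab[i0, j0] <- cur
    while (length(queue)) {
      cell <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (di in -1:1) for (dj in -1:1) {
        i <- cell[1] + di; j <- cell[2] + dj
        if (i >= 1L && i <= nr && j >= 1L && j <= nc &&
            mask[i, j] && lab[i, j] == 0L) {
          lab[i, j] <- cur
          queue[[length(queue) + 1L]] <- c(i, j)
        }
      }
    }
  }
  lab
}

#' Detect interface hotspots in a consensus matrix
#'
#' A hotspot is a maximal 8-connected component of matrix cells whose
#' contact frequency is at least `freq_threshold`; components smaller
#' than `min_size` cells are discarded.  The numeric rule operationalises
#' the qualitative notion of a consistently predicted contact patch; all
#' three knobs are exposed.
#'
#' @param matrix a `consensus_matrix`.
#' @param freq_threshold minimum frequency of member cells (default 0.5).
#' @param min_size minimum number of member cells (default 3).
#' @return List of `hotspot` objects sorted by `peak_freq` (then
#'   `mean_freq`) descending, each with `bait_residues`, `prey_residues`,
#'   `cells` (data.frame of member pairs), `peak_freq`, `mean_freq`,
#'   `n_cells`.
#' @export
detect_hotspots <- function(matrix, freq_threshold = 0.5, min_size = 3L) {
  stopifnot(inherits(matrix, "consensus_matrix"))
  if (!(freq_threshold > 0 && freq_threshold <= 1))
    stop_slimscan("freq_threshold must be in (0,1]", "slimscan_config_error")
  mask <- !is.na(matrix$freq) & matrix$freq >= freq_threshold
  if (!any(mask)) return(list())
  lab <- label_components8(mask)
  out <- list()
  for (k in seq_len(max(lab))) {
    idx <- which(lab == k, arr.ind = TRUE)
    if (nrow(idx) < min_size) next
    cells <- data.frame(bait_idx = matrix$bait_idx[idx[, 1]],
                        prey_idx = matrix$prey_idx[idx[, 2]],
                        freq = matrix$freq[idx])
    out[[length(out) + 1L]] <- structure(
      list(bait_residues = sort(unique(cells$bait_idx)),
           prey_residues = sort(unique(cells$prey_idx)),
           cells = cells[order(cells$bait_idx, cells$prey_idx), ],
           peak_freq = max(cells$freq), mean_freq = mean(cells$freq),
           n_cells = nrow(cells)),
      class = "hotspot")
  }
  ord <- order(vapply(out, `[[`, 0, "peak_freq"),
               vapply(out, `[[`, 0, "mean_freq"), decreasing = TRUE)
  out[ord]
}

#' @export
print.hotspot <- function(x, ...) {
  cat(sprintf("<hotspot: bait %s, prey %s, %d cells, peak %.3f, mean %.3f>\n",
              paste(range(x$bait_residues), collapse = "-"),
              paste(range(x$prey_residues), collapse = "-"),
              x$n_cells, x$peak_freq, x$mean_freq))
  invisible(x)
}

#' Write a consensus matrix as long-format TSV
#'
#' Columns `bait_idx`, `prey_idx`, `hits`, `denom`, `freq`; one row per
#' cell with a positive denominator.
#'
#' @param matrix a `consensus_matrix`.
#' @param path output TSV.
#' @param provenance optional named list echoed as header comments.
#' @return `path`, invisibly.
#' @export
write_consensus <- function(matrix, path, provenance = NULL) {
  idx <- which(matrix$denom > 0, arr.ind = TRUE)
  df <- data.frame(bait_idx = matrix$bait_idx[idx[, 1]],
                   prey_idx = matrix$prey_idx[idx[, 2]],
                   hits = matrix$hits[idx], denom = matrix$denom[idx],
                   freq = matrix$freq[idx])
  df <- df[order(df$bait_idx, df$prey_idx), ]
  write_tsv_prov(df, path, c(list(bait_domain = matrix$bait_name,
                                  n_runs = matrix$n_runs,
                                  denominator = matrix$denominator),
                             provenance))
}

#' Plot a consensus matrix as a heatmap
#'
#' Prey residues on rows, bait residues on columns, frequency as colour.
#' Cosmetic convenience; the TSV matrix is the canonical output.
#'
#' @param matrix a `consensus_matrix` (typically after
#'   [observed_submatrix()]).
#' @param ... passed to [graphics::image()].
#' @return Invisibly, the plotted frequency matrix.
#' @export
plot_consensus <- function(matrix, ...) {
  stopifnot(inherits(matrix, "consensus_matrix"))
  z <- matrix$freq  # dim: bait (x) by prey (y)
  graphics::image(x = seq_along(matrix$bait_idx), y = seq_along(matrix$prey_idx),
                  z = z, zlim = c(0, 1),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = sprintf("%s residue", matrix$bait_name),
                  ylab = "prey residue", axes = FALSE, ...)
  graphics::axis(1, at = seq_along(matrix$bait_idx), labels = matrix$bait_idx,
                 las = 2, cex.axis = 0.6)
  graphics::axis(2, at = seq_along(matrix$prey_idx), labels = matrix$prey_idx,
                 las = 1, cex.axis = 0.6)
  graphics::box()
  invisible(matrix$freq)
}
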