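# shared fixtures and independent oracles

# build a two-chain model directly from coordinate rows:
# each row of `df`: role, resno, x, y, z (single-atom "residues" unless
# elety given)
tiny_model <- function(df, elety = NULL) {
  atoms <- data.frame(
    role = df$role,
    chain = ifelse(df$role == "bait", "A", "B"),
    resno = df$resno, resid = "ALA",
    elety = if (is.null(elety)) "CA" else elety,
    x = df$x, y = df$y, z = df$z, stringsAsFactors = FALSE)
  structure_model(atoms)
}

# independent brute-force contact oracle: plain double loop over all
# inter-chain atom pairs, no vectorised linear algebra
brute_force_contacts <- function(model, cutoff, inclusive = FALSE,
                                 heavy_only = TRUE) {
  at <- model$atoms
  if (heavy_only) at <- at[!at$hydrogen, ]
  b <- at[at$role == "bait", ]
  p <- at[at$role == "prey", ]
  res <- list()
  for (i in unique(b$resno)) for (j in unique(p$resno)) {
    bi <- b[b$resno == i, ]
    pj <- p[p$resno == j, ]
    dmin <- Inf
    for (k in seq_len(nrow(bi))) for (l in seq_len(nrow(pj))) {
      d <- sqrt((bi$x[k] - pj$x[l])^2 + (bi$y[k] - pj$y[l])^2 +
                  (bi$z[k] - pj$z[l])^2)
      if (d < dmin) dmin <- d
    }
    hit <- if (inclusive) dmin <= cutoff else dmin < cutoff
    if (hit) res[[length(res) + 1L]] <- data.frame(bait_idx = i, prey_idx = j,
                                                   min_dist = dmin)
  }
  if (!length(res)) return(data.frame(bait_idx = integer(),
                                      prey_idx = integer(),
                                      min_dist = numeric()))
  out <- do.call(rbind, res)
  out[order(out$bait_idx, out$prey_idx), ]
}

# random two-chain model: nb/np residues, 1-3 atoms each, coordinates in
# a box scaled so some pairs fall under typical cutoffs
random_model <- function(nb = 6, np = 6, box = 12, seed = 1) {
  set.seed(seed)
  mk <- function(role, n) {
    rows <- lapply(seq_len(n), function(r) {
      k <- sample(1:3, 1)
      data.frame(role = role, resno = r,
                 elety = c("CA", "CB", "CG")[seq_len(k)],
                 x = runif(k, 0, box), y = runif(k, 0, box),
                 z = runif(k, 0, box), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  df <- rbind(mk("bait", nb), mk("prey", np))
  df$chain <- ifelse(df$role == "bait", "A", "B")
  df$resid <- "ALA"
  structure_model(df)
}

contact_key <- function(cs) paste(cs$bait_idx, cs$prey_idx)

# standard worked scan: 39-aa tail from residue 63, three bait domains
worked_manifest <- function() {
  frags <- enumerate_fragments(scan_config(span(63, 101)))
  build_manifest(frags, list(eTD0 = span(420, 540), eTD1 = span(700, 820),
                             eTD2 = span(890, 1010)))
}

# run the contacts stage over a mock-scan directory tree
scan_runs <- function(manifest, dir, cutoff = 5) {
  lapply(seq_len(nrow(manifest)), function(r) {
    e <- as.list(manifest[r, ])
    m <- load_structure(select_top_model(file.path(dir, e$run_id)))
    list(entry = e, contacts = remap_contacts(interchain_contacts(m, cutoff), e))
  })
}

# independent superposition oracle: coarse Euler-angle grid search
# refined with general-purpose numerical optimisation
oracle_rmsd <- function(mobile, target) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(target, 2, colMeans(target))
  rot <- function(ang) {
    ca <- cos(ang); sa <- sin(ang)
    Rz1 <- matrix(c(ca[1], sa[1], 0, -sa[1], ca[1], 0, 0, 0, 1), 3)
    Ry <- matrix(c(ca[2], 0, -sa[2], 0, 1, 0, sa[2], 0, ca[2]), 3)
    Rz2 <- matrix(c(ca[3], sa[3], 0, -sa[3], ca[3], 0, 0, 0, 1), 3)
    Rz2 %*% Ry %*% Rz1
  }
  obj <- function(ang) sqrt(mean(rowSums((A %*% t(rot(ang)) - B)^2)))
  grid <- expand.grid(a = seq(0, 2 * pi, by = pi / 6),
                      b = seq(0, pi, by = pi / 6),
                      c = seq(0, 2 * pi, by = pi / 6))
  vals <- apply(grid, 1, obj)
  best <- as.numeric(grid[which.min(vals), ])
  fit <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  fit$value
}
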