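# toy trajectory with two planted pairs, used throughout
md_spec <- function(...) toy_complex_spec(5, 10,
                                          data.frame(bait_idx = c(2, 3),
                                                     prey_idx = c(9, 9)), ...)

test_that("frame contacts equal the brute-force oracle under the inclusive rule", {
  tr <- make_toy_trajectory(toy_trajectory_spec(md_spec(), n_frames = 3,
                                                jitter_sigma = 0.3, seed = 5))
  for (f in 1:3) {
    got <- frame_contacts(tr, f, cutoff = 4.5)
    m <- structure_model(slimscan:::frame_atoms(tr, f))
    want <- brute_force_contacts(m, cutoff = 4.5, inclusive = TRUE)
    expect_equal(contact_key(got), contact_key(want))
  }
  expect_error(frame_contacts(tr, 9), class = "slimscan_bounds_error")
})

test_that("contact maps count frame fractions and respect construction", {
  # static, fully bound: map equals the single-frame 0/1 indicator
  tr <- make_toy_trajectory(toy_trajectory_spec(md_spec(), n_frames = 4))
  map <- trajectory_contact_map(tr)
  ind <- frame_contacts(tr, 1)
  expect_equal(sum(map$freq == 1), nrow(ind))
  expect_true(all(map$freq %in% c(0, 1)))
  # half-bound, even frame count, zero jitter: planted pairs at exactly 0.5
  tr2 <- make_toy_trajectory(toy_trajectory_spec(md_spec(), n_frames = 10,
                                                 bound_fraction = 0.5))
  map2 <- trajectory_contact_map(tr2)
  expect_equal(map2$freq["2", "9"], 0.5)
  expect_equal(map2$freq["3", "9"], 0.5)
  expect_equal(sum(map2$freq), 1.0)  # nothing else ever in contact
  # one-frame trajectory: binary map
  tr1 <- make_toy_trajectory(toy_trajectory_spec(md_spec(), n_frames = 1))
  expect_true(all(trajectory_contact_map(tr1)$freq %in% c(0, 1)))
})

test_that("concatenating trajectories frame-weights their maps", {
  tra <- make_toy_trajectory(toy_trajectory_spec(md_spec(), n_frames = 4,
                                                 bound_fraction = 1))
  trb <- make_toy_trajectory(toy_trajectory_spec(md_spec(), n_frames = 8,
                                                 bound_fraction = 0.25))
  cat_coords <- array(c(tra$coords, trb$coords),
                      dim = c(nrow(tra$topology), 3, 12))
  trc <- slimscan:::new_trajectory(tra$topology, cat_coords)
  mc <- trajectory_contact_map(trc)
  ma <- trajectory_contact_map(tra); mb <- trajectory_contact_map(trb)
  expect_equal(mc$freq, (4 * ma$freq + 8 * mb$freq) / 12)
})

test_that("average_maps is an elementwise mean with strict axis checks", {
  tr <- lapply(c(1, 0), function(bf)
    trajectory_contact_map(make_toy_trajectory(
      toy_trajectory_spec(md_spec(), n_frames = 4, bound_fraction = bf))))
  avg <- average_maps(tr)
  expect_equal(avg$freq["2", "9"], 0.5)
  expect_equal(avg$n_replicates, 2L)
  # idempotent on identical inputs, invariant to order
  expect_equal(average_maps(list(tr[[1]], tr[[1]]))$freq, tr[[1]]$freq)
  expect_equal(average_maps(rev(tr))$freq, avg$freq)
  # replicate bound fractions 0.1..1.0 average to 0.55 at the planted cell
  maps <- lapply(seq(0.1, 1, by = 0.1), function(bf)
    trajectory_contact_map(make_toy_trajectory(
      toy_trajectory_spec(md_spec(), n_frames = 10, bound_fraction = bf))))
  expect_equal(average_maps(maps)$freq["2", "9"], 0.55)
  # axis mismatch is a shape error
  other <- trajectory_contact_map(make_toy_trajectory(
    toy_trajectory_spec(toy_complex_spec(4, 10), n_frames = 2)))
  expect_error(average_maps(list(tr[[1]], other)), class = "slimscan_shape_error")
})

test_that("marginal profiles are row and column sums of the map", {
  map <- slimscan:::new_contact_map(c(10L, 11L), c(1L, 2L),
                                    matrix(c(1, 0.5, 0, 0.5), 2, 2,
                                           byrow = TRUE),
                                    10L, 1L)
  mp <- marginal_profiles(map)
  expect_equal(unname(mp$bait), c(1.5, 0.5))
  expect_equal(unname(mp$prey), c(1.0, 1.0))
  expect_equal(sum(mp$bait), sum(map$freq))
  expect_equal(sum(mp$prey), sum(map$freq))
  # all-zero map gives zero profiles
  z <- slimscan:::new_contact_map(1L, 1L, matrix(0, 1, 1), 1L, 1L)
  expect_equal(unname(marginal_profiles(z)$bait), 0)
})

test_that("hydrogen-bond series track distance, angle and persistence", {
  # hand-built two-frame trajectory: D-H...A nearly linear then far apart
  top <- data.frame(role = c("bait", "bait", "prey"),
                    chain = c("A", "A", "B"), resno = c(1L, 1L, 2L),
                    resid = "SER", elety = c("OG", "HG", "O"),
                    stringsAsFactors = FALSE)
  top <- structure_model(top |> transform(x = 0, y = 0, z = 0))$atoms
  co <- array(0, dim = c(3, 3, 2))
  co[, , 1] <- rbind(c(0, 0, 0), c(0.96, 0, 0), c(2.9, 0.3, 0))  # engaged
  co[, , 2] <- rbind(c(0, 0, 0), c(0.96, 0, 0), c(4.0, 0, 0))    # too far
  tr <- slimscan:::new_trajectory(top, co)
  hb <- hbond_series(tr, donor = list(resno = 1, elety = "OG", role = "bait"),
                     acceptor = list(resno = 2, elety = "O", role = "prey"),
                     hydrogen = list(resno = 1, elety = "HG", role = "bait"))
  expect_equal(length(hb$distance), 2L)
  expect_equal(hb$distance[2], 4.0)
  expect_true(hb$angle[1] > 150)
  expect_equal(hb$engaged, c(TRUE, FALSE))
  expect_equal(hb$persistence, 0.5)
  # distance-only criterion when no hydrogen is given
  hb2 <- hbond_series(tr, donor = list(resno = 1, elety = "OG", role = "bait"),
                      acceptor = list(resno = 2, elety = "O", role = "prey"))
  expect_null(hb2$angle)
  expect_equal(hb2$persistence, 0.5)
  # tight angle cutoff breaks the bent geometry
  co[, , 1] <- rbind(c(0, 0, 0), c(0.96, 0, 0), c(0.96, 3.0, 0))  # ~90 deg
  tr90 <- slimscan:::new_trajectory(top, co)
  hb90 <- hbond_series(tr90, donor = list(resno = 1, elety = "OG", role = "bait"),
                       acceptor = list(resno = 2, elety = "O", role = "prey"),
                       hydrogen = list(resno = 1, elety = "HG", role = "bait"))
  expect_false(hb90$engaged[1])
  expect_error(
    hbond_series(tr, donor = list(resno = 7, elety = "OG", role = "bait"),
                 acceptor = list(resno = 2, elety = "O", role = "prey")),
    class = "slimscan_lookup_error")
})

test_that("anchoring classification counts in-pocket frame fractions", {
  full <- make_toy_trajectory(toy_trajectory_spec(md_spec(), n_frames = 10))
  r <- classify_anchored(full, motif_residue = 9, pocket_residues = c(2, 3))
  expect_equal(r$in_pocket_fraction, 1.0)
  expect_true(r$anchored)
  # planted unbinding at the midpoint: fraction 0.5, still anchored at 0.5
  half <- make_toy_trajectory(toy_trajectory_spec(md_spec(), n_frames = 10,
                                                  unbinding_frame = 5))
  r2 <- classify_anchored(half, 9, c(2, 3), frame_fraction_threshold = 0.5)
  expect_equal(r2$in_pocket_fraction, 0.5)
  expect_true(r2$anchored)
  # a residue with only backbone atoms cannot define side-chain anchoring
  expect_error(classify_anchored(full, motif_residue = 1,
                                 pocket_residues = c(2, 3)),
               class = "slimscan_definition_error")
})

test_that("trajectory multi-model PDB round-trips through the readers", {
  tr <- make_toy_trajectory(toy_trajectory_spec(md_spec(), n_frames = 5,
                                                bound_fraction = 0.6,
                                                jitter_sigma = 0.05, seed = 8))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(tr, f)
  tr2 <- read_trajectory(f)
  expect_equal(n_frames(tr2), 5L)
  expect_equal(tr2$topology$resno, tr$topology$resno)
  expect_equal(tr2$coords, tr$coords, tolerance = 1e-3)
  expect_equal(trajectory_contact_map(tr2)$freq,
               trajectory_contact_map(tr)$freq)
  # table-keyed construction agrees with the direct array
  tab <- do.call(rbind, lapply(1:5, function(f)
    data.frame(frame = f, atom = seq_len(nrow(tr$topology)),
               x = tr$coords[, 1, f], y = tr$coords[, 2, f],
               z = tr$coords[, 3, f])))
  tr3 <- trajectory_from_table(tr$topology, tab)
  expect_equal(tr3$coords, tr$coords)
})
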