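test_that("the model contact rule is strictly less-than at the cutoff", {
  two <- function(d) tiny_model(data.frame(
    role = c("bait", "prey"), resno = c(1L, 1L),
    x = c(0, d), y = 0, z = 0))
  expect_equal(nrow(interchain_contacts(two(4.99), cutoff = 5)), 1L)
  expect_equal(nrow(interchain_contacts(two(5.00), cutoff = 5)), 0L)
  # the trajectory rule is inclusive at its boundary
  expect_equal(nrow(interchain_contacts(two(4.5), cutoff = 4.5,
                                        inclusive = TRUE)), 1L)
  expect_equal(nrow(interchain_contacts(two(4.6), cutoff = 4.5,
                                        inclusive = TRUE)), 0L)
})

test_that("contact extraction matches the brute-force atom-pair oracle", {
  for (seed in 1:25) {
    m <- random_model(nb = 5, np = 5, box = 10, seed = seed)
    got <- interchain_contacts(m, cutoff = 5)
    want <- brute_force_contacts(m, cutoff = 5)
    expect_equal(contact_key(got), contact_key(want))
    expect_equal(got$min_dist, want$min_dist, tolerance = 1e-12)
  }
  # larger single model
  m <- random_model(nb = 25, np = 25, box = 25, seed = 99)
  got <- interchain_contacts(m, cutoff = 6)
  want <- brute_force_contacts(m, cutoff = 6)
  expect_equal(contact_key(got), contact_key(want))
})

test_that("contacts are monotone in cutoff and invariant to rigid motion", {
  m <- random_model(nb = 8, np = 8, box = 14, seed = 3)
  for (pair in list(c(3, 5), c(4, 6), c(5, 8))) {
    small <- contact_key(interchain_contacts(m, pair[1]))
    large <- contact_key(interchain_contacts(m, pair[2]))
    expect_true(all(small %in% large))
  }
  # rotate + translate every atom: distances unchanged, set identical
  th <- 0.9
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  xyz <- as.matrix(m$atoms[, c("x", "y", "z")]) %*% t(R)
  m2 <- m
  m2$atoms$x <- xyz[, 1] + 11; m2$atoms$y <- xyz[, 2] - 4; m2$atoms$z <- xyz[, 3] + 2
  expect_equal(contact_key(interchain_contacts(m2, 5)),
               contact_key(interchain_contacts(m, 5)))
})

test_that("hydrogens are excluded by the heavy-atom rule but counted on request", {
  atoms <- data.frame(
    role = c("bait", "prey", "prey"), chain = c("A", "B", "B"),
    resno = c(1L, 1L, 1L), resid = "ALA",
    elety = c("CA", "CA", "HB1"),
    x = c(0, 7, 4), y = 0, z = 0, stringsAsFactors = FALSE)
  m <- structure_model(atoms)
  expect_true(m$atoms$hydrogen[3])
  expect_equal(nrow(interchain_contacts(m, 5, heavy_only = TRUE)), 0L)
  expect_equal(nrow(interchain_contacts(m, 5, heavy_only = FALSE)), 1L)
  # heavy-only never yields more contacts than all-atom
  for (seed in 1:5) {
    m <- random_model(6, 6, 10, seed)
    expect_true(all(contact_key(interchain_contacts(m, 5, heavy_only = TRUE)) %in%
                      contact_key(interchain_contacts(m, 5, heavy_only = FALSE))))
  }
})

test_that("load_structure keeps the two named chains and flags problems", {
  d <- withr::local_tempdir()
  f <- file.path(d, "abc.pdb")
  bio3d::write.pdb(file = f, xyz = as.vector(t(matrix(c(
    0, 0, 0,   1.5, 0, 0,   20, 0, 0,   24, 0, 0,   50, 50, 50), ncol = 3, byrow = TRUE))),
    resno = c(1, 2, 1, 2, 1), chain = c("A", "A", "B", "B", "C"),
    resid = rep("GLY", 5), elety = rep("CA", 5))
  expect_warning(m <- load_structure(f, "A", "B"), "dropping chain")
  expect_equal(sort(unique(m$atoms$chain)), c("A", "B"))
  expect_equal(sum(m$atoms$role == "bait"), 2L)
  expect_error(load_structure(f, "A", "Z"), class = "slimscan_format_error")
  expect_error(load_structure(file.path(d, "missing.pdb")),
               class = "slimscan_format_error")
})

test_that("structure write/load round-trips a toy complex", {
  spec <- toy_complex_spec(4, 6, data.frame(bait_idx = 2, prey_idx = 5))
  f <- withr::local_tempfile(fileext = ".pdb")
  m <- make_toy_complex(spec, path = f)
  m2 <- load_structure(f)
  expect_equal(nrow(m2$atoms), nrow(m$atoms))
  expect_equal(m2$atoms$resno, m$atoms$resno)
  expect_equal(m2$atoms[, c("x", "y", "z")], m$atoms[, c("x", "y", "z")],
               tolerance = 1e-3)  # PDB fixed-width coordinates
  expect_equal(contact_key(interchain_contacts(m2, 5)),
               contact_key(interchain_contacts(m, 5)))
})

test_that("select_top_model follows the ranking, not file name order", {
  d <- withr::local_tempdir()
  spec <- toy_complex_spec(3, 3, data.frame(bait_idx = 1, prey_idx = 1))
  write_structure(make_toy_complex(spec), file.path(d, "model_1.pdb"))
  write_structure(make_toy_complex(spec), file.path(d, "model_2.pdb"))
  jsonlite::write_json(list(run_id = "r1", ranking = c("model_2", "model_1"),
                            confidence = 0.5),
                       file.path(d, "metadata.json"), auto_unbox = TRUE)
  expect_equal(basename(select_top_model(d)), "model_2.pdb")
  # missing referenced model is an error naming the run
  jsonlite::write_json(list(run_id = "r1", ranking = c("model_9"),
                            confidence = 0.5),
                       file.path(d, "metadata.json"), auto_unbox = TRUE)
  expect_error(select_top_model(d), "r1", class = "slimscan_run_error")
})

test_that("run metadata is validated and PAE is optional", {
  d <- withr::local_tempdir()
  jsonlite::write_json(list(run_id = "r", ranking = "m", confidence = 0.87),
                       file.path(d, "metadata.json"), auto_unbox = TRUE)
  meta <- load_run_metadata(d)
  expect_equal(meta$confidence, 0.87)
  expect_null(meta$pae)
  jsonlite::write_json(list(run_id = "r", ranking = "m", confidence = 1.3),
                       file.path(d, "metadata.json"), auto_unbox = TRUE)
  expect_error(load_run_metadata(d), class = "slimscan_validation_error")
  jsonlite::write_json(list(run_id = "r", ranking = "m", confidence = 0.5,
                            pae = matrix(1, 4, 4)),
                       file.path(d, "metadata.json"))
  expect_equal(dim(load_run_metadata(d)$pae), c(4L, 4L))
  expect_error(load_run_metadata(withr::local_tempdir()),
               class = "slimscan_run_error")
})

test_that("the AlphaFold ranking_debug dialect resolves to ranked_0", {
  d <- withr::local_tempdir()
  jsonlite::write_json(
    list(`iptm+ptm` = list(model_1 = 0.62, model_2 = 0.87),
         order = c("model_2", "model_1")),
    file.path(d, "ranking_debug.json"), auto_unbox = TRUE)
  spec <- toy_complex_spec(3, 3, data.frame(bait_idx = 1, prey_idx = 1))
  write_structure(make_toy_complex(spec), file.path(d, "ranked_0.pdb"))
  write_structure(make_toy_complex(spec), file.path(d, "ranked_1.pdb"))
  meta <- load_run_metadata(d)
  expect_equal(meta$confidence, 0.87)
  expect_equal(basename(select_top_model(d)), "ranked_0.pdb")
})

test_that("remap_contacts shifts local indices to global coordinates", {
  cs <- slimscan:::new_contact_set(
    data.frame(bait_idx = 43L, prey_idx = 5L, min_dist = 4.2),
    "fragment_local", 5, FALSE, TRUE)
  frag <- list(global_start = 95L, global_end = 101L,
               bait_start = 700L, bait_end = 820L)
  g <- remap_contacts(cs, frag)
  expect_equal(g$prey_idx, 99L)
  expect_equal(g$bait_idx, 742L)
  expect_equal(attr(g, "frame"), "global")
  # indices beyond the fragment or domain are mapping errors
  bad <- slimscan:::new_contact_set(
    data.frame(bait_idx = 1L, prey_idx = 9L, min_dist = 4),
    "fragment_local", 5, FALSE, TRUE)
  expect_error(remap_contacts(bad, frag), class = "slimscan_mapping_error")
  expect_error(remap_contacts(g, frag), class = "slimscan_mapping_error")
  # whole-tail fragment: pure offset by the tail start
  spec <- toy_complex_spec(4, 6, data.frame(bait_idx = c(2, 3), prey_idx = c(4, 6)))
  m <- make_toy_complex(spec)
  local <- interchain_contacts(m, 5)
  g2 <- remap_contacts(local, list(global_start = 63L, global_end = 68L,
                                   bait_start = 700L, bait_end = 703L))
  expect_equal(g2$prey_idx, local$prey_idx + 62L)
  expect_equal(g2$bait_idx, local$bait_idx + 699L)
})
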