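test_that("interchange format round-trips and converts units", {
  ens <- tiny_ensemble(c(-10, 0.123456789, 5),
                       c("A_NH_2", "A_NH_2", "A_NH_3"),
                       freqs = c(100, 500, 1500))
  path <- withr::local_tempfile(fileext = ".json")
  write_ensemble(ens, path)
  back <- read_ensemble(path)
  expect_equal(nrow(back), 3L)
  expect_equal(back$energy, ens$energy, tolerance = 1e-12)
  expect_equal(back$coords, ens$coords)
  expect_equal(back$freqs, ens$freqs)

  # hartree input converted on read
  doc <- jsonlite::read_json(path)
  doc$conformers[[1]]$energy <- list(value = -1.0, unit = "hartree")
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  expect_equal(read_ensemble(path)$energy[1], -2625.4996,
               tolerance = 1e-12)

  doc$conformers[[1]]$energy <- list(value = 1, unit = "furlongs")
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  expect_error(read_ensemble(path), "unknown energy unit")

  doc$conformers[[1]]$energy <- NULL
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  expect_error(read_ensemble(path), "record 1")
})

test_that("duplicate conformer ids are rejected", {
  expect_error(
    tiny_ensemble(c(0, 1), c("A_NH_2", "A_NH_2"), ids = c("c1", "c1")),
    "duplicate")
})

test_that("keep_lowest retains the n lowest per isomer, ties by id", {
  ens <- tiny_ensemble(c(5, 1, 3, 2, 4), rep("A_NH_2", 5))
  kept <- keep_lowest(ens, 2)
  expect_equal(kept$energy, c(1, 2))

  two <- tiny_ensemble(c(3, 1, 2, 6, 4, 5),
                       rep(c("A_NH_2", "A_NH_3"), each = 3))
  expect_equal(nrow(keep_lowest(two, 2)), 4L)

  tie <- tiny_ensemble(c(1, 1, 1), rep("A_NH_2", 3),
                       ids = c("b", "a", "c"))
  expect_equal(keep_lowest(tie, 2)$id, c("a", "b"))
  # n larger than group: whole group kept
  expect_equal(nrow(keep_lowest(ens, 99)), 5L)
})

test_that("energy-window filtering keeps structures near the minimum", {
  ens <- tiny_ensemble(c(0, 15, 25), rep("A_NH_2", 3))
  expect_equal(nrow(filter_energy_window(ens, 20, "global")), 2L)
  expect_equal(nrow(filter_energy_window(ens, 40, "global")), 3L)
  one <- tiny_ensemble(0, "A_NH_2")
  expect_equal(nrow(filter_energy_window(one, 1)), 1L)
  expect_equal(nrow(filter_energy_window(ens[0, ], 20)), 0L)

  # per-isomer scope uses each isomer's own minimum
  two <- tiny_ensemble(c(0, 25, 100, 110),
                       rep(c("A_NH_2", "A_NH_3"), each = 2))
  expect_equal(nrow(filter_energy_window(two, 20, "per_isomer")), 3L)
  expect_equal(nrow(filter_energy_window(two, 20, "global")), 1L)
})

test_that("Kabsch RMSD is zero under rigid motions and symmetric", {
  withr::local_seed(11)
  for (rep in 1:5) {
    xyz <- synth_geometry(8, seed = NULL)
    a <- make_conf(rep("C", 8), xyz)
    moved <- xyz %*% random_rotation() +
      matrix(stats::runif(3, -5, 5), 8, 3, byrow = TRUE)
    b <- make_conf(rep("C", 8), moved)
    expect_lt(kabsch_rmsd(a, b), 1e-9)
    xyz2 <- synth_geometry(8, seed = NULL)
    c2 <- make_conf(rep("C", 8), xyz2)
    expect_equal(kabsch_rmsd(a, c2), kabsch_rmsd(c2, a),
                 tolerance = 1e-9)
    # rigid motion of either argument leaves the RMSD unchanged
    expect_equal(kabsch_rmsd(b, c2), kabsch_rmsd(a, c2),
                 tolerance = 1e-9)
  }
  single <- make_conf("C", matrix(c(1, 2, 3), 1))
  single2 <- make_conf("C", matrix(c(9, 9, 9), 1))
  expect_equal(kabsch_rmsd(single, single2), 0)
  expect_error(
    kabsch_rmsd(make_conf(c("C", "N"), matrix(0, 2, 3)),
                make_conf(c("N", "C"), matrix(0, 2, 3))),
    "element sequences differ")
})

test_that("Kabsch RMSD matches a brute-force rotation search", {
  withr::local_seed(7)
  base <- matrix(c(0, 0, 0, 1.4, 0, 0, 0, 1.4, 0, 0.5, 0.5, 1.2),
                 4, 3, byrow = TRUE)
  displaced <- base
  displaced[2, ] <- displaced[2, ] + c(0.4, 0, 0)
  a <- make_conf(rep("C", 4), base)
  b <- make_conf(rep("C", 4), displaced)
  expect_equal(kabsch_rmsd(a, b), rmsd_bruteforce(base, displaced),
               tolerance = 1e-6)
  for (rep in 1:3) {
    x <- synth_geometry(5, seed = NULL, box = 4)
    y <- x + matrix(stats::rnorm(15, 0, 0.3), 5, 3)
    expect_equal(kabsch_rmsd(make_conf(rep("C", 5), x),
                             make_conf(rep("C", 5), y)),
                 rmsd_bruteforce(x, y), tolerance = 1e-6)
  }
})

test_that("hydrogens are excluded from the default heavy-atom RMSD", {
  el <- c("C", "C", "C", "H")
  base <- matrix(c(0, 0, 0, 1.5, 0, 0, 0, 1.5, 0, 1, 1, 1), 4, 3,
                 byrow = TRUE)
  moved <- base
  moved[4, ] <- moved[4, ] + 5  # only the hydrogen moves
  a <- make_conf(el, base); b <- make_conf(el, moved)
  expect_lt(kabsch_rmsd(a, b, "heavy"), 1e-9)
  expect_gt(kabsch_rmsd(a, b, "all"), 1)
})

test_that("align score is the calibrated exponential of the RMSD", {
  expect_equal(align_score(0), 1.0)
  expect_equal(align_score(0.0202), 0.980, tolerance = 1e-3)
  expect_equal(align_score(1.0), exp(-1), tolerance = 1e-12)
  expect_error(align_score(-0.1), "non-negative")
  rmsds <- seq(0, 3, by = 0.25)
  expect_true(all(diff(align_score(rmsds)) < 0))
})

test_that("deduplication keeps one member of each duplicate pair", {
  xyz <- synth_geometry(6, seed = 3)
  dup <- function(e1, e2, coords2 = xyz) {
    conformer_ensemble(tibble::tibble(
      id = c("a", "b"), isomer_label = "A_NH_2", stage = "dft",
      energy = c(e1, e2),
      elements = rep(list(rep("C", 6)), 2),
      coords = list(xyz, coords2), freqs = list(NULL, NULL)
    ))
  }
  # identical geometries within the energy gate: lower-energy survivor
  d <- deduplicate(dup(0.0, 0.01))
  expect_equal(d$id, "a")
  # energy gate fails: both kept
  expect_equal(nrow(deduplicate(dup(0.0, 0.05))), 2L)
  # geometry differs (RMSD 0.5 => score 0.607): both kept
  shifted <- xyz
  shifted[1, ] <- shifted[1, ] + 1.2
  r <- kabsch_rmsd(make_conf(rep("C", 6), xyz),
                   make_conf(rep("C", 6), shifted))
  expect_lt(align_score(r), 0.98)
  expect_equal(nrow(deduplicate(dup(0.0, 0.0, shifted))), 2L)
})

test_that("deduplication and window filtering are idempotent and shrink", {
  withr::local_seed(21)
  xyz <- synth_geometry(6, seed = NULL)
  ens <- conformer_ensemble(tibble::tibble(
    id = sprintf("c%d", 1:6),
    isomer_label = rep(c("A_NH_2", "A_NH_3"), each = 3),
    stage = "dft",
    energy = c(0, 0.01, 0.02, 5, 5.005, 30),
    elements = rep(list(rep("C", 6)), 6),
    coords = list(xyz, perturb_geometry(xyz, 0.003, seed = NULL),
                  perturb_geometry(xyz, 2, seed = NULL),
                  xyz, perturb_geometry(xyz, 0.003, seed = NULL), xyz),
    freqs = rep(list(NULL), 6)
  ))
  d1 <- deduplicate(ens)
  expect_lte(nrow(d1), nrow(ens))
  expect_identical(deduplicate(d1)$id, d1$id)
  f1 <- filter_energy_window(ens, 20)
  expect_identical(filter_energy_window(f1, 20)$id, f1$id)
  # transitive chain collapses to a single survivor
  expect_equal(sum(d1$isomer_label == "A_NH_2"), 2L)  # near-dup removed
  expect_equal(sum(d1$isomer_label == "A_NH_3"), 2L)
})

test_that("keep_lowest commutes with a window that spares its members", {
  ens <- tiny_ensemble(c(0, 1, 2, 50), rep("A_NH_2", 4))
  a <- keep_lowest(filter_energy_window(ens, 20), 2)
  b <- keep_lowest(ens, 2)
  expect_true(all(a$id %in% b$id))
})

test_that("XYZ export writes a well-formed block", {
  ens <- tiny_ensemble(0, "A_NH_2", ids = "c01")
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(ens, "c01", path)
  lines <- readLines(path)
  expect_equal(as.integer(lines[1]), 4L)
  expect_length(lines, 6L)
  expect_error(write_xyz(ens, "nope", tempfile()), "no conformer")
})
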