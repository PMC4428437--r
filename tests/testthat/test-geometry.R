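test_that("CA-only loading splits domains by inclusive residue intervals", {
  path <- tempfile(fileext = ".pdb")
  write_fixture_pdb(603, path)
  g <- load_chaperone_ca(path)
  expect_equal(nrow(g$nbd), 384)   # residues 4..387
  expect_equal(nrow(g$sbd), 207)   # residues 397..603
  expect_equal(nrow(g$linker), 9)  # residues 388..396
  expect_identical(g$provenance, "pdb")
  expect_silent(validate_chaperone_geometry(g))
  unlink(path)
})

test_that("a missing CA raises an error naming the residue", {
  path <- tempfile(fileext = ".pdb")
  write_fixture_pdb(603, path)
  lines <- readLines(path)
  drop <- grepl("^ATOM", lines) &
    as.integer(substr(lines, 23, 26)) == 400 & !is.na(
      suppressWarnings(as.integer(substr(lines, 23, 26))))
  writeLines(lines[!drop], path)
  expect_error(load_chaperone_ca(path), "400")
  expect_error(load_chaperone_ca(path, nbd_range = c(10, 4)), "interval")
  unlink(path)
})

test_that("fixture PDB round-trips coordinates at PDB precision", {
  g <- fixture_geom_small()
  path <- tempfile(fileext = ".pdb")
  write_fixture_pdb(g, path)
  nb <- nrow(g$nbd)
  nl <- nrow(g$linker)
  g2 <- load_chaperone_ca(path, nbd_range = c(1, nb),
                          linker_range = c(nb + 1, nb + nl),
                          sbd_range = c(nb + nl + 1,
                                        nb + nl + nrow(g$sbd)))
  expect_lt(max(abs(g2$nbd - g$nbd)), 1e-3)
  expect_lt(max(abs(g2$sbd - g$sbd)), 1e-3)
  expect_error(write_fixture_pdb(0, tempfile()), "empty")
  unlink(path)
})

test_that("attachment superposes the clamp exactly and is idempotent", {
  ff <- ff_params()
  geom <- fixture_geom_small()
  conf <- build_complex(10, geom, ff)
  # clamp rigidity: intra-unit distances of substrate beads 1-7 match the
  # clamp sites exactly
  expect_equal(as.vector(dist(conf$substrate[1:7, ])),
               as.vector(dist(geom$clamp_sites)), tolerance = 1e-9)
  # attach -> detach -> attach reproduces identical coordinates
  conf2 <- attach_chaperone(detach_chaperone(conf), geom)
  expect_equal(conf2$substrate, conf$substrate, tolerance = 1e-12)
  expect_equal(conf2$nbd, conf$nbd, tolerance = 1e-12)
  expect_error(build_complex(7, geom, ff), "binding site not exposed")
  # rigid transforms preserve intra-domain distances (attachment is one)
  expect_lt(max(abs(dist(conf$nbd) - dist(geom$nbd))), 1e-9)
  expect_lt(max(abs(dist(conf$sbd) - dist(geom$sbd))), 1e-9)
})

test_that("overlap indicator is a strict z < 0 test on chaperone beads only", {
  ff <- ff_params()
  conf <- build_complex(10, fixture_geom_small(), ff)
  up <- conf
  for (f in c("nbd", "sbd", "linker")) up[[f]][, 3] <- up[[f]][, 3] + 100
  expect_false(check_overlap(up))
  one <- up
  one$nbd[5, 3] <- -0.1
  expect_true(check_overlap(one))
  # beads exactly on the wall plane do not overlap (boundary convention)
  onwall <- up
  onwall$nbd[, 3] <- 0
  expect_false(check_overlap(onwall))
  # substrate below the wall is a sampler bug, not an overlap
  bad <- up
  bad$substrate[2, 3] <- -1
  expect_error(check_overlap(bad), "wall")
})

test_that("overlap indicator is invariant under rotations about z", {
  ff <- ff_params()
  conf <- build_complex(12, fixture_geom_small(), ff)
  base <- check_overlap(conf)
  for (th in c(0.7, 2.1, 4.4)) {
    Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                 3, 3, byrow = TRUE)
    rot <- conf
    for (f in c("substrate", "nbd", "sbd", "linker")) {
      rot[[f]] <- rot[[f]] %*% t(Rz)
    }
    expect_identical(check_overlap(rot), base)
  }
})

test_that("sampled conformations stay wall-legal, tethered and rigid", {
  ff <- ff_params()
  geom <- fixture_geom_small()
  tr <- sample_overlap_trace(12, geom, ff,
                             sampler_config(n_sweeps = 1000, seed = 3))
  fin <- tr$metadata$final_conformation
  expect_true(all(fin$substrate[, 3] >= 0))
  expect_equal(fin$substrate[12, ], c(0, 0, 0), tolerance = 1e-12)
  d <- sqrt(rowSums((fin$substrate[-1, ] - fin$substrate[-12, ])^2))
  expect_true(all(abs(d - ff$bond_length) < 0.2 * ff$bond_length))
  # rigidity after ~2.4e4 attempted moves
  expect_lt(max(abs(dist(fin$nbd) - dist(geom$nbd))), 1e-6)
  expect_lt(max(abs(dist(fin$sbd) - dist(geom$sbd))), 1e-6)
})

test_that("synthetic chaperone geometry satisfies its invariants", {
  g <- fixture_geom()
  # every clamp site within 8 A of an SBD bead (validator enforces this)
  expect_silent(validate_chaperone_geometry(g))
  ext <- chaperone_extent(g)
  expect_gt(ext, 80)
  expect_lt(ext, 120)
  expect_error(build_synthetic_chaperone(nbd_radius = 2), "degenerate")
})
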