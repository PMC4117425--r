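# Fixture generator: determinism, analytic truths, and spec validation.

test_that("generation is deterministic and files byte-stable", {
  f1 <- generate_fixture(fixture_spec("gated_cavity"))
  f2 <- generate_fixture(fixture_spec("gated_cavity"))
  expect_identical(f1$structure$atoms, f2$structure$atoms)
  p1 <- tempfile(fileext = ".pdb"); p2 <- tempfile(fileext = ".pdb")
  write_fixture(f1, p1); write_fixture(f2, p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
})

test_that("analytic truths match the declared geometry", {
  expect_equal(generate_fixture(fixture_spec("spherical_cavity",
                                             radius = 5))$truth$volume,
               4 / 3 * pi * 125, tolerance = 1e-12)
  expect_equal(generate_fixture(fixture_spec("hemispherical_pocket",
                                             radius = 4))$truth$volume,
               2 / 3 * pi * 64, tolerance = 1e-12)
  expect_false(generate_fixture(fixture_spec("slab"))$truth$site_exists)
  g <- generate_fixture(fixture_spec("gated_cavity"))$truth
  expect_lte(g$closed_volume, g$closed_volume_max)
  expect_gte(g$open_volume, 160)
})

test_that("fixtures are legal PDB files exercising the real I/O path", {
  fix <- generate_fixture(fixture_spec("gated_cavity"))
  path <- tempfile(fileext = ".pdb")
  write_fixture(fix, path, truth_path = tempfile(fileext = ".json"))
  s <- read_structure(path)
  expect_equal(nrow(s$atoms), nrow(fix$structure$atoms))
  expect_lt(max(abs(as.matrix(s$atoms[, c("x", "y", "z")]) -
                      as.matrix(fix$structure$atoms[, c("x", "y", "z")]))), 1e-3)
  # pseudo-residue chain is long enough to satisfy the cryptic size rule
  expect_gte(max(fix$structure$n_residues_per_chain), 100)
})

test_that("infeasible specs are rejected", {
  expect_error(fixture_spec("spherical_cavity", radius = -1))
  expect_error(fixture_spec("spherical_cavity", polar_fraction = 2))
  expect_error(fixture_spec("no_such_kind"))
})

test_that("the gated fixture has a clash-free open rotamer for its gate", {
  fix <- generate_fixture(fixture_spec("gated_cavity"))
  atoms <- fix$structure$atoms
  gate <- atoms[atoms$resid == "LYS", ]
  wall <- atoms[atoms$resid != "LYS", ]
  open_chis <- fix$truth$gate$open_chis
  open_res <- set_residue_chis(gate, open_chis)
  d <- as.matrix(dist(rbind(as.matrix(open_res[, c("x", "y", "z")]),
                            as.matrix(wall[, c("x", "y", "z")]))))
  cross <- d[seq_len(nrow(open_res)), -seq_len(nrow(open_res))]
  expect_gt(min(cross), 2.8)   # no vdW overlap deeper than the clash margin
})

test_that("phobic/philic normalization constants match the reference fixture", {
  fix <- generate_fixture(fixture_spec("reference_pocket"))
  s <- fix$structure
  cfg <- detection_config()
  det <- detect_sites(s, cfg)
  site <- det$sites[[1]]
  raw <- flexsite:::polarity_kernels(site$points, s, cfg)
  expect_equal(mean(raw$phobic), flexsite:::.phobic_norm, tolerance = 1e-6)
  expect_equal(mean(raw$philic), flexsite:::.philic_norm, tolerance = 1e-6)
  # normalized site means are 1 by construction
  d <- site$descriptors
  expect_equal(d$h, 1, tolerance = 1e-6)
  expect_equal(d$p, 1, tolerance = 1e-6)
})
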