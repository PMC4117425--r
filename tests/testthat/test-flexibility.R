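# Probes, docking, side-chain repacking and the flexible-result aggregation.

test_that("packaged probes have the declared composition", {
  naph <- load_probe("naphthalene")
  expect_equal(sum(!naph$is_h), 10)
  expect_true(all(naph$element[!naph$is_h] == "C"))
  expect_length(naph$rotatable, 0)              # rigid
  # planarity of the ring system
  hv <- naph$xyz[!naph$is_h, ]
  pc <- prcomp(hv)
  expect_lt(pc$sdev[3], 0.1)

  tsn <- load_probe("tsn")
  expect_equal(round(tsn$molecular_weight), 363)
  expect_equal(sum(!tsn$is_h), 27)
  expect_gte(length(tsn$rotatable), 4)
  confs <- probe_conformers(tsn, flex_config(max_conformers = 4))
  expect_lte(length(confs), 4)
  expect_gte(length(confs), 1)
})

test_that("naphthalene docks into the centre of a snug spherical cavity", {
  # at radius 2.6 the clash-free region confines the centroid near the centre
  fix <- generate_fixture(fixture_spec("spherical_cavity", radius = 2.6))
  det <- detect_sites(fix$structure)
  poses <- dock_probe(fix$structure, det$sites[[1]], load_probe("naphthalene"))
  expect_gt(length(poses), 0)
  expect_lt(sqrt(sum(poses[[1]]$centroid^2)), 1.5)
  expect_true(all(diff(vapply(poses, function(p) p$energy, numeric(1))) >= 0))
})

test_that("a 2 A cavity cannot hold naphthalene", {
  fix <- generate_fixture(fixture_spec("spherical_cavity", radius = 2))
  det <- detect_sites(fix$structure, detection_config(mingroup = 5))
  expect_gt(length(det$sites), 0)
  poses <- dock_probe(fix$structure, det$sites[[1]], load_probe("naphthalene"))
  expect_length(poses, 0)
})

test_that("docking is deterministic", {
  fix <- generate_fixture(fixture_spec("spherical_cavity", radius = 4))
  det <- detect_sites(fix$structure)
  p1 <- dock_probe(fix$structure, det$sites[[1]], load_probe("naphthalene"))
  p2 <- dock_probe(fix$structure, det$sites[[1]], load_probe("naphthalene"))
  expect_identical(p1, p2)
})

test_that("repacking far from any residue is a no-op", {
  fix <- generate_fixture(fixture_spec("spherical_cavity", radius = 3))
  naph <- load_probe("naphthalene")
  pose <- list(xyz = sweep(naph$xyz, 2, c(80, 80, 80), "+"),
               element = naph$element, is_h = naph$is_h, energy = -1)
  rp <- repack_side_chains(fix$structure, pose)
  expect_equal(rp$structure$atoms, fix$structure$atoms)
  expect_equal(nrow(rp$moved_residues), 0)
  expect_equal(rp$backbone_rmsd, 0)
})

test_that("the gated fixture's blocking residue adopts the open rotamer", {
  fix <- generate_fixture(fixture_spec("gated_cavity"))
  det <- detect_sites(fix$structure)
  site <- det$sites[[1]]
  trimmed <- flexsite:::trim_side_chains(fix$structure, site$points, 5)
  poses <- dock_probe(trimmed, site, load_probe("naphthalene"))
  expect_gt(length(poses), 0)
  rp <- repack_side_chains(fix$structure, poses[[1]])
  expect_false(is.null(rp))
  expect_true(any(rp$moved_residues$resid == "LYS"))
  expect_lte(rp$backbone_rmsd, 1.5)
  # chain moved out of the pocket: its atoms are farther from the centre
  before <- fix$structure$atoms
  after <- rp$structure$atoms
  lys_b <- before[before$resid == "LYS" & before$elety == "NZ", c("x", "y", "z")]
  lys_a <- after[after$resid == "LYS" & after$elety == "NZ", c("x", "y", "z")]
  expect_gt(sqrt(sum(as.numeric(lys_a)^2)), sqrt(sum(as.numeric(lys_b)^2)))
})

test_that("flexible_result returns the top-scoring model, volume tie-break", {
  mk <- function(dp, v) list(rescored = list(
    volume = v, descriptors = list(dscore_plus_reported = dp, e = 0.9)))
  models <- list(mk(1.8, 200), mk(2.1, 240), mk(1.9, 150), mk(2.0, 300))
  fr <- flexible_result(models)
  expect_equal(fr$dscore_plus_flex, 2.1)
  expect_equal(fr$volume_flex, 240)
  expect_equal(flexible_result(list(mk(1.7, 99)))$volume_flex, 99)
  tie <- flexible_result(list(mk(2.0, 100), mk(2.0, 180)))
  expect_equal(tie$volume_flex, 180)
  expect_null(flexible_result(list(list(rescored = NULL))))
})

test_that("rotamer machinery sets chi angles it reports", {
  tmpl <- flexsite:::aa_templates()
  tt <- tmpl[tmpl$resname == "LEU" & tmpl$element != "H", ]
  res <- data.frame(type = "ATOM", eleno = seq_len(nrow(tt)), elety = tt$atom,
                    resid = "LEU", chain = "A", resno = 1L, insert = "",
                    x = tt$x, y = tt$y, z = tt$z, o = 1, b = 0,
                    element = tt$element, is_het = FALSE)
  target <- c(60, 175) * pi / 180
  res2 <- set_residue_chis(res, target)
  got <- flexsite:::residue_chi_values(res2)
  expect_equal(sin(got), sin(target), tolerance = 1e-6)
  expect_equal(cos(got), cos(target), tolerance = 1e-6)
  # backbone fixed
  bb <- res$elety %in% c("N", "CA", "C", "O", "CB")
  expect_equal(res2[bb, c("x", "y", "z")], res[bb, c("x", "y", "z")])
})
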