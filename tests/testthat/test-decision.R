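# Gates and classification labels, interface annotation, and published
# per-structure examples from the protein-protein interaction benchmark.

test_that("rigid gate is a strict threshold on the reported score", {
  expect_false(rigid_gate(0.9))   # low-scoring interface site stays behind
  expect_false(rigid_gate(1.3))   # boundary is exclusive
  expect_true(rigid_gate(1.5))
})

test_that("published benchmark rows classify as printed", {
  # Bcl-xL 2bzw: opens from 112 to 172 A^3 under flexibility -> druggable
  r <- classify("2bzw", 1, rigid = list(dscore_plus = 1.5, V = 112, e = 90),
                flexible = list(dscore_plus = 2.4, V = 172), chain_residues = 150)
  expect_equal(r$label, "druggable_flexible")   # V 112 > 100: not cryptic
  # IL-2R alpha 1pw6: volume never reaches the drug-like range
  r <- classify("1pw6", 1, rigid = list(dscore_plus = 1.4, V = 73, e = 90),
                flexible = list(dscore_plus = 1.4, V = 72), chain_residues = 150)
  expect_equal(r$label, "difficult")
  # a small, not fully buried pocket that opens: cryptic
  r <- classify("x", 1, rigid = list(dscore_plus = 1.5, V = 90, e = 88),
                flexible = list(dscore_plus = 1.9, V = 200), chain_residues = 150)
  expect_equal(r$label, "cryptic_druggable")
})

test_that("cryptic label requires every branch of the rule", {
  rigid <- list(dscore_plus = 1.5, V = 90, e = 88)
  flex <- list(dscore_plus = 1.9, V = 200)
  expect_equal(classify("x", 1, rigid, flex, 150)$label, "cryptic_druggable")
  # fully buried initial pocket
  r2 <- rigid; r2$e <- 97
  expect_equal(classify("x", 1, r2, flex, 150)$label, "druggable_flexible")
  # too large initially
  r3 <- rigid; r3$V <- 112
  expect_equal(classify("x", 1, r3, flex, 150)$label, "druggable_flexible")
  # protein too small
  expect_equal(classify("x", 1, rigid, flex, 80)$label, "druggable_flexible")
  # strict-mode enclosure comparison
  r4 <- rigid; r4$e <- 96
  expect_equal(classify("x", 1, r4, flex, 150)$label, "cryptic_druggable")
  cfg_strict <- decision_config(cryptic_enclosure_strict = TRUE)
  expect_equal(classify("x", 1, r4, flex, 150, cfg_strict)$label,
               "druggable_flexible")
})

test_that("remaining labels: oversized, not advanced, rigid-only", {
  expect_equal(classify("x", 1, list(dscore_plus = 2.0, V = 900, e = 80))$label,
               "oversized_site")
  expect_equal(classify("x", 1, list(dscore_plus = 1.1, V = 300, e = 80))$label,
               "not_advanced")
  r <- classify("x", 1, list(dscore_plus = 1.6, V = 300, e = 80))
  expect_equal(r$label, "druggable_rigid")
  expect_true(r$rigid_druggable)
  expect_equal(classify("x", 1, list(dscore_plus = 1.6, V = 120, e = 80))$label,
               "difficult")
  expect_error(classify("x", 1, NULL, list(dscore_plus = 2, V = 200)),
               "inconsistent")
})

test_that("interface annotation flags TSN contacts and ligand overlap", {
  # two short chains 8 A apart; fake TSN pose touching chain B
  atoms <- data.frame(
    type = "ATOM", eleno = 1:6, elety = "C1", resid = "UNK",
    chain = rep(c("A", "B"), each = 3), resno = rep(1:3, 2), insert = "",
    x = c(0, 1.5, 3, 8, 9.5, 11), y = 0, z = 0, o = 1, b = 0,
    element = "C", is_het = FALSE, stringsAsFactors = FALSE)
  s <- structure(list(atoms = atoms, removed_ligand_atoms = NULL),
                 class = c("prepared_structure", "flexsite_structure"))
  site <- list(points = matrix(c(1, 0, 0), 1, 3), centroid = c(1, 0, 0))
  rec <- classify("x", 1, list(dscore_plus = 1.8, V = 200, e = 80),
                  list(dscore_plus = 1.8, V = 200), 150)
  pose_near <- list(xyz = matrix(c(6.2, 0, 0), 1, 3), is_h = FALSE)
  got <- annotate_interfaces(rec, s, site, pose_near, site_chain = "A")
  expect_true(got$ppi_interface)   # 6.2 is 1.8 A from the chain-B atom at 8
  pose_far <- list(xyz = matrix(c(4.5, 0, 0), 1, 3), is_h = FALSE)
  got2 <- annotate_interfaces(rec, s, site, pose_far, site_chain = "A")
  expect_false(got2$ppi_interface)

  # removed ligand overlapping the site cells
  s$removed_ligand_atoms <- data.frame(element = "C", x = 1, y = 0, z = 0)
  got3 <- annotate_interfaces(rec, s, site, NULL, site_chain = "A")
  expect_true(got3$ligand_pocket)
  expect_gt(got3$ligand_overlap_A3, 0)
  # isolated site, no ligand atoms nearby
  s$removed_ligand_atoms <- data.frame(element = "C", x = 40, y = 0, z = 0)
  expect_false(annotate_interfaces(rec, s, site, NULL,
                                   site_chain = "A")$ligand_pocket)
})

test_that("batch records are independent of processing order", {
  p1 <- tempfile(fileext = ".pdb"); p2 <- tempfile(fileext = ".pdb")
  write_fixture(generate_fixture(fixture_spec("spherical_cavity", radius = 3)), p1)
  write_fixture(generate_fixture(fixture_spec("slab")), p2)
  # rigid-only analysis: keep the comparison about record assembly
  cfg <- run_config(decision = decision_config(rigid_gate = 99))
  t1 <- records_table(run_batch(c(p1, p2), cfg))
  t2 <- records_table(run_batch(c(p2, p1), cfg))
  ord <- function(t) t[order(t$structure_id, t$site_id), ]
  rownames(t1) <- rownames(t2) <- NULL
  expect_equal(ord(t1), ord(t2))
})
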