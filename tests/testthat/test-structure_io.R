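# Reading, preparation rules (waters, ligand MW ceiling, cofactor keep-list,
# hydrogens), monomer selection, and round-tripping.

test_that("keep-list holds the heme variants plus zinc and magnesium", {
  expect_setequal(default_keep_list(),
                  c("HEM", "MHM", "HEV", "VER", "SRM", "HEO", "HEB", "HEC",
                    "HDM", "HDD", "DDH", "ZN", "MG"))
})

test_that("monomer mode returns one protein chain with its het groups", {
  path <- write_mini_protein(tempfile(fileext = ".pdb"), chains = c("A", "B"),
                             het = het_ring("LIG", 8, near = c(6, 0, 0)))
  s <- read_structure(path, "monomer", chain = "A")
  expect_equal(unique(s$atoms$chain[!s$atoms$is_het]), "A")
  # the het ring sits near chain A, so it is assigned to the A monomer
  expect_true(any(s$atoms$resid == "LIG"))
  sB <- read_structure(path, "monomer", chain = "B")
  expect_false(any(sB$atoms$resid == "LIG"))
  expect_error(read_structure(path, "monomer", chain = "Z"), "not found")
})

test_that("C-alpha-only structures are rejected", {
  path <- write_mini_protein(tempfile(fileext = ".pdb"), chains = "A",
                             ca_only = TRUE)
  expect_error(read_structure(path), class = "flexsite_calpha_error")
})

test_that("structures survive a write/read round trip within 1e-3 A", {
  path <- write_mini_protein(tempfile(fileext = ".pdb"), chains = "A")
  s <- read_structure(path)
  out <- tempfile(fileext = ".pdb")
  write_structure(s, out)
  s2 <- read_structure(out)
  expect_equal(nrow(s2$atoms), nrow(s$atoms))
  expect_lt(max(abs(as.matrix(s2$atoms[, c("x", "y", "z")]) -
                      as.matrix(s$atoms[, c("x", "y", "z")]))), 1e-3)
})

test_that("preparation removes waters and small ligands but keeps HEM", {
  path <- write_mini_protein(tempfile(fileext = ".pdb"), chains = "A",
                             with_water = TRUE,
                             het = het_ring("HEM", 10, near = c(8, 4, 0)))
  s <- read_structure(path)
  prep <- prepare(s)
  expect_false(any(toupper(prep$atoms$resid) == "HOH"))
  expect_true("HEM" %in% prep$retained_cofactors)
  expect_true(any(prep$atoms$resid == "HEM"))

  # a ~300 Da carbon ring is a ligand and is removed (and recorded)
  path2 <- write_mini_protein(tempfile(fileext = ".pdb"), chains = "A",
                              het = het_ring("LIG", 20, near = c(8, 4, 0)))
  prep2 <- prepare(read_structure(path2))
  expect_false(any(prep2$atoms$resid == "LIG"))
  expect_equal(prep2$removed_ligands$resid, "LIG")
  expect_lte(prep2$removed_ligands$mw, 1000)
})

test_that("oversized het entities are retained and flagged", {
  path <- write_mini_protein(tempfile(fileext = ".pdb"), chains = "A",
                             het = het_ring("MCY", 95, near = c(25, 0, 0)))
  prep <- prepare(read_structure(path))
  expect_true("MCY" %in% prep$oversized_het)
  expect_true(any(prep$atoms$resid == "MCY"))
  expect_equal(nrow(prep$removed_ligands), 0)
})

test_that("preparation is idempotent and only adds atoms", {
  path <- write_mini_protein(tempfile(fileext = ".pdb"), chains = "A",
                             with_water = TRUE)
  s <- read_structure(path)
  p1 <- prepare(s)
  expect_gte(nrow(p1$atoms), sum(!s$atoms$is_het))
  p2 <- prepare(p1)
  expect_equal(nrow(p2$atoms), nrow(p1$atoms))
  expect_equal(sort(paste(p2$atoms$resno, p2$atoms$elety)),
               sort(paste(p1$atoms$resno, p1$atoms$elety)))
})

test_that("het molecular weight is computed from composition", {
  # 20 ring carbons with implicit hydrogens: between 240 and 320 Da
  path <- write_mini_protein(tempfile(fileext = ".pdb"), chains = "A",
                             het = het_ring("LIG", 20, near = c(9, 0, 0)))
  prep <- prepare(read_structure(path))
  expect_gt(prep$removed_ligands$mw, 20 * 12)
  expect_lt(prep$removed_ligands$mw, 20 * 12 + 20 * 2)
})
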