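# Grid geometry, probe energy field, enclosure ray casting and site-point
# marking, checked against closed-form values and brute-force oracles.

rotation_about_test <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

single_atom_structure <- function(xyz = c(0, 0, 0), element = "C") {
  atoms <- data.frame(type = "ATOM", eleno = 1L, elety = "C1", resid = "UNK",
                      chain = "A", resno = 1L, insert = "", x = xyz[1],
                      y = xyz[2], z = xyz[3], o = 1, b = 0, element = element,
                      is_het = FALSE, stringsAsFactors = FALSE)
  structure(list(atoms = atoms, source = "test"),
            class = c("prepared_structure", "flexsite_structure"))
}

multi_atom_structure <- function(xyz, element = "C") {
  atoms <- data.frame(type = "ATOM", eleno = seq_len(nrow(xyz)),
                      elety = paste0(element, seq_len(nrow(xyz))),
                      resid = "UNK", chain = "A",
                      resno = (seq_len(nrow(xyz)) - 1) %/% 3 + 1, insert = "",
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], o = 1, b = 0,
                      element = element, is_het = FALSE, stringsAsFactors = FALSE)
  structure(list(atoms = atoms, source = "test"),
            class = c("prepared_structure", "flexsite_structure"))
}

test_that("inside flags match a brute-force distance check", {
  # small helix-like fragment
  t_ <- seq(0, 3 * pi, length.out = 10)
  s <- multi_atom_structure(cbind(2.3 * cos(t_), 2.3 * sin(t_), 1.5 * t_ / pi))
  cfg <- detection_config(grid_spacing = 0.9, margin = 4)
  g <- build_grid(s, cfg)
  xyz <- heavy_xyz(s)
  oracle <- apply(g$coords, 1, function(p)
    any(sqrt(colSums((t(xyz) - p)^2)) <= 1.70))
  expect_equal(as.logical(g$inside), unname(oracle))
})

test_that("grid covers the structure with the configured margin", {
  s <- single_atom_structure()
  cfg <- detection_config(grid_spacing = 0.5, margin = 8)
  g <- build_grid(s, cfg)
  expect_true(all(g$origin <= -8))
  expect_true(all(g$origin + (g$dims - 1) * g$spacing >= 8))
  expect_error(build_grid(s, detection_config(grid_spacing = 0.05,
                                              max_points = 1e5)),
               "memory budget")
})

test_that("probe energy field matches the pair potential in closed form", {
  s <- single_atom_structure()
  cfg <- detection_config()
  g <- build_grid(s, detection_config(grid_spacing = 1.0, margin = 10))
  g <- vdw_energy_field(g, s, cfg)
  # at the pair minimum distance (4 A) the energy is minus the well depth
  at_min <- which(abs(g$coords[, 1] - 4) < 1e-6 &
                    abs(g$coords[, 2]) < 1e-6 & abs(g$coords[, 3]) < 1e-6)
  expect_equal(g$vdw[at_min], -0.15, tolerance = 1e-10)
  # beyond the cutoff the field is exactly zero
  far <- which(abs(g$coords[, 1] - 9) < 1e-6 & abs(g$coords[, 2]) < 1e-6 &
                 abs(g$coords[, 3]) < 1e-6)
  expect_identical(g$vdw[far], 0)
  # inside the receptor envelope: sentinel
  expect_true(is.infinite(g$vdw[which(g$inside)[1]]))
})

test_that("energy at a midpoint equals the sum of the two pair terms", {
  s <- multi_atom_structure(rbind(c(-3, 0, 0), c(3, 0, 0)))
  g <- build_grid(s, detection_config(grid_spacing = 1.0, margin = 6))
  g <- vdw_energy_field(g, s, detection_config())
  mid <- which(rowSums(abs(g$coords)) < 1e-6)
  pair <- function(r) 0.15 * ((4 / r)^12 - 2 * (4 / r)^6)
  expect_equal(g$vdw[mid], 2 * pair(3), tolerance = 1e-10)
})

test_that("enclosure is 1 inside a closed shell and 0 in empty space", {
  fix <- generate_fixture(fixture_spec("spherical_cavity", radius = 3))
  e <- enclosure_at(rbind(c(0, 0, 0), c(60, 60, 60)), fix$structure)
  expect_equal(e[1], 1.0)
  expect_equal(e[2], 0.0)
})

test_that("enclosure is invariant under rigid rotation within 0.02", {
  fix <- generate_fixture(fixture_spec("hemispherical_pocket", radius = 4))
  s <- fix$structure
  pts <- rbind(c(0, 0, 0), c(0, 0, -2), c(1, 1, -1))
  e0 <- enclosure_at(pts, s)
  R <- rotation_about_test(c(1, 2, 3), 0.9)
  s2 <- s
  s2$atoms[, c("x", "y", "z")] <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(R)
  e1 <- enclosure_at(pts %*% t(R), s2)
  expect_lt(max(abs(e0 - e1)), 0.02)
})

test_that("phobic and philic potentials match a brute-force kernel sum", {
  # mixed lining: carbons and oxygens
  xyz <- rbind(c(3, 0, 0), c(-3, 0, 0), c(0, 3, 0), c(0, -3, 0), c(0, 0, 3))
  s <- multi_atom_structure(xyz, element = c("C", "C", "O", "O", "C"))
  cfg <- detection_config()
  raw <- flexsite:::polarity_kernels(rbind(c(0, 0, 0), c(1, 0.5, 0)), s, cfg)
  for (i in 1:2) {
    p <- rbind(c(0, 0, 0), c(1, 0.5, 0))[i, ]
    expect_equal(raw$phobic[i],
                 oracle_kernel_sum(p, xyz[c(1, 2, 5), , drop = FALSE],
                                   rep(1, 3), 6), tolerance = 1e-12)
    expect_equal(raw$philic[i],
                 oracle_kernel_sum(p, xyz[3:4, , drop = FALSE], rep(1, 2), 6),
                 tolerance = 1e-12)
  }
  # a point surrounded only by carbons has zero philic potential
  s_c <- multi_atom_structure(xyz, element = "C")
  raw_c <- flexsite:::polarity_kernels(matrix(0, 1, 3), s_c, cfg)
  expect_identical(raw_c$philic, 0)
  # no atoms within the kernel cutoff: both zero
  far <- flexsite:::polarity_kernels(matrix(50, 1, 3), s, cfg)
  expect_identical(far$phobic, 0)
  expect_identical(far$philic, 0)
})

test_that("site-point marking equals re-evaluating the three predicates", {
  fix <- generate_fixture(fixture_spec("hemispherical_pocket", radius = 3.5))
  cfg <- detection_config()
  g <- compute_site_grid(fix$structure, cfg)
  idx <- which(g$candidate)
  oracle <- !g$inside[idx] & g$enclosure[idx] >= cfg$enclosure_min &
    g$vdw[idx] <= -cfg$maxvdw
  expect_equal(g$is_site_point[idx], oracle)
  expect_false(any(g$is_site_point[-idx]))
})

test_that("raising maxvdw shrinks the site-point set monotonically", {
  fix <- generate_fixture(fixture_spec("spherical_cavity", radius = 3))
  g <- compute_site_grid(fix$structure, detection_config())
  for (mv in c(1.2, 1.5, 2.0)) {
    g2 <- mark_site_points(g, detection_config(maxvdw = mv))
    expect_true(all(which(g2$is_site_point) %in% which(g$is_site_point)))
    g <- g2
  }
})

test_that("deeper cavities never have less enclosed site points", {
  means <- sapply(c(60, 40, 20), function(mouth) {
    fix <- generate_fixture(fixture_spec("spherical_cavity", radius = 3,
                                         mouth_angle = mouth))
    det <- detect_sites(fix$structure)
    det$sites[[1]]$descriptors$e
  })
  expect_true(all(diff(means) >= -1e-9))
})

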