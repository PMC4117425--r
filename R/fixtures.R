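# Synthetic receptor fixtures with analytic ground truth: protein-like atom
# clouds (pseudo-residues in legal PDB records, shell packing at ~1.8 A
# spacing) realizing cavities of controlled volume, enclosure, lining
# composition, and a rotamer-gated "cryptic" corridor.
#
# Wall placement uses the probe standoff: the detectable free region of a
# cavity ends where the probe potential against a dense carbon wall crosses
# zero, at rmin_pair / 5^(1/6) (~3.06 A for the 4.0 A probe-carbon pair
# minimum, from the integrated flat-wall 10-4 form of the 6-12 potential).
# Wall atom centers therefore sit at (cavity radius + standoff), so the
# analytically-truthed cavity radius matches the detectable region.

#' Probe wall standoff
#'
#' Distance from a dense carbon wall at which the probe potential crosses
#' zero: `rmin_pair / 5^(1/6)`.
#' @return standoff in Angstrom
#' @export
wall_standoff <- function() {
  (.probe_params$rmin2 + element_rmin2("C")) / 5^(1 / 6)
}

.shell_spacing <- 1.8
.atom_area <- sqrt(3) / 2 * .shell_spacing^2   # hexagonal packing area/atom

shell_xyz <- function(center, R) {
  n <- max(12, round(4 * pi * R^2 / .atom_area))
  sweep(fibonacci_sphere(n) * R, 2, center, "+")
}

# hexagonal-packed plane patch at height z
plane_xyz <- function(z, half_x, half_y) {
  dy <- .shell_spacing * sqrt(3) / 2
  ys <- seq(-half_y, half_y, by = dy)
  out <- list()
  for (i in seq_along(ys)) {
    off <- if (i %% 2 == 0) .shell_spacing / 2 else 0
    xs <- seq(-half_x + off, half_x, by = .shell_spacing)
    out[[i]] <- cbind(xs, ys[i], z)
  }
  do.call(rbind, out)
}

# cylinder shell around the x axis
cylinder_xyz <- function(R, x0, x1, center_yz = c(0, 0)) {
  n_ring <- max(6, round(2 * pi * R / .shell_spacing))
  dx <- .shell_spacing * sqrt(3) / 2
  xs <- seq(x0, x1, by = dx)
  out <- list()
  for (i in seq_along(xs)) {
    off <- if (i %% 2 == 0) pi / n_ring else 0
    th <- 2 * pi * (seq_len(n_ring) - 1) / n_ring + off
    out[[i]] <- cbind(xs[i], center_yz[1] + R * cos(th), center_yz[2] + R * sin(th))
  }
  do.call(rbind, out)
}

# drop points closer than `lim` to each other (keeps first occurrences)
dedupe_xyz <- function(xyz, lim = 1.0) {
  if (nrow(xyz) < 2) return(xyz)
  keep <- !duplicated(round(xyz / lim))
  xyz[keep, , drop = FALSE]
}

#' Specify a synthetic receptor fixture
#'
#' @param kind one of `spherical_cavity`, `hemispherical_pocket`, `slab`,
#'   `two_cavity`, `gated_cavity`, `reference_pocket`
#' @param radius main cavity radius (A)
#' @param radius2 second cavity / lobe radius (A), where applicable
#' @param polar_fraction fraction of inner-wall atoms that are polar oxygens
#' @param mouth_angle half-angle (degrees) of a mouth cone carved into a
#'   spherical cavity wall (0 = closed)
#' @param seed integer recorded with the fixture (generation is
#'   deterministic)
#' @return `fixture_spec`
#' @export
fixture_spec <- function(kind = c("spherical_cavity", "hemispherical_pocket",
                                  "slab", "two_cavity", "gated_cavity",
                                  "reference_pocket"),
                         radius = 4, radius2 = 3, polar_fraction = 0,
                         mouth_angle = 0, seed = 0L) {
  kind <- match.arg(kind)
  stopifnot(radius > 0, radius2 > 0, polar_fraction >= 0, polar_fraction <= 1)
  structure(list(kind = kind, radius = radius, radius2 = radius2,
                 polar_fraction = polar_fraction, mouth_angle = mouth_angle,
                 seed = as.integer(seed)), class = "fixture_spec")
}

#' Generate a fixture structure and its ground truth
#'
#' Deterministic for a given spec. The structure is a `prepared_structure`
#' whose pseudo-residues hold three wall atoms each; the gated fixture adds
#' one real lysine gate residue whose side chain crosses the cavity, with a
#' wall recess molded around the open rotamer.
#'
#' @param spec a [fixture_spec()]
#' @return list with `structure` and `truth` (volumes in A^3, mouth center,
#'   site-existence flags)
#' @export
generate_fixture <- function(spec) {
  st <- wall_standoff()
  switch(spec$kind,
    spherical_cavity = fixture_sphere(spec, st),
    two_cavity = fixture_two_cavity(spec, st),
    slab = fixture_slab(spec),
    hemispherical_pocket = fixture_hemisphere(spec, st),
    reference_pocket = fixture_hemisphere(
      fixture_spec("hemispherical_pocket",
                   radius = (300 * 3 / (2 * pi))^(1 / 3),
                   polar_fraction = 1 / 3, seed = spec$seed), st),
    gated_cavity = fixture_gated(spec, st)
  )
}

fixture_sphere <- function(spec, st) {
  r <- spec$radius
  inner <- shell_xyz(c(0, 0, 0), r + st)
  outer <- shell_xyz(c(0, 0, 0), r + st + .shell_spacing)
  if (spec$mouth_angle > 0) {
    ang <- spec$mouth_angle * pi / 180
    keep <- function(m) m[acos(pmin(1, m[, 3] / sqrt(rowSums(m^2)))) > ang, , drop = FALSE]
    inner <- keep(inner); outer <- keep(outer)
  }
  xyz <- rbind(inner, outer)
  el <- lining_elements(nrow(inner), nrow(outer), spec$polar_fraction)
  truth <- list(volume = 4 / 3 * pi * r^3,
                enclosure = if (spec$mouth_angle == 0) 1.0 else NA_real_,
                mouth_center = if (spec$mouth_angle > 0) c(0, 0, 0),
                site_exists = TRUE, n_sites = 1L)
  list(structure = fixture_structure(xyz, el), truth = truth)
}

fixture_two_cavity <- function(spec, st) {
  r1 <- spec$radius; r2 <- spec$radius2
  gap <- 12
  c2 <- c(r1 + r2 + 2 * (st + .shell_spacing) + gap, 0, 0)
  xyz <- rbind(shell_xyz(c(0, 0, 0), r1 + st),
               shell_xyz(c(0, 0, 0), r1 + st + .shell_spacing),
               shell_xyz(c2, r2 + st),
               shell_xyz(c2, r2 + st + .shell_spacing))
  el <- rep("C", nrow(xyz))
  truth <- list(volume = 4 / 3 * pi * max(r1, r2)^3,
                volumes = 4 / 3 * pi * sort(c(r1, r2), decreasing = TRUE)^3,
                site_exists = TRUE, n_sites = 2L)
  list(structure = fixture_structure(xyz, el), truth = truth)
}

fixture_slab <- function(spec) {
  # finite patch, sized so every point over the flat faces keeps an
  # enclosure fraction below the site-point threshold
  xyz <- rbind(plane_xyz(0, 5, 5), plane_xyz(-.shell_spacing, 5, 5))
  truth <- list(volume = 0, site_exists = FALSE, n_sites = 0L)
  list(structure = fixture_structure(xyz, rep("C", nrow(xyz))), truth = truth)
}

# An open bowl: the lower half of a double spherical shell. The exterior is
# convex everywhere, so the pocket interior is the only enclosed region.
fixture_hemisphere <- function(spec, st) {
  r <- spec$radius
  Rs <- r + st
  inner <- shell_xyz(c(0, 0, 0), Rs)
  inner <- inner[inner[, 3] < 0.3, , drop = FALSE]
  outer <- shell_xyz(c(0, 0, 0), Rs + .shell_spacing)
  outer <- outer[outer[, 3] < 0.3, , drop = FALSE]
  xyz <- rbind(inner, outer)
  el <- lining_elements(nrow(inner), nrow(outer), spec$polar_fraction)
  truth <- list(volume = 2 / 3 * pi * r^3, mouth_center = c(0, 0, 0),
                site_exists = TRUE, n_sites = 1L)
  list(structure = fixture_structure(xyz, el), truth = truth)
}

# Gated "cryptic" fixture: a drug-like spherical cavity whose centre is
# crossed by a lysine side chain anchored in the wall. In the closed state
# the chain's exclusion halo reduces the detectable pocket to a thin ring
# well under the cryptic volume ceiling; any probe docked into the pocket
# must overlap the chain, and the only clash-free rotamer swings it into a
# wall recess molded around the open conformation, restoring the full
# drug-like cavity.
fixture_gated <- function(spec, st) {
  r <- 3.8
  dist_f <- function(m) sqrt(rowSums(m^2)) - r
  inner <- shell_xyz(c(0, 0, 0), r + st)
  outer <- shell_xyz(c(0, 0, 0), r + st + .shell_spacing)
  wall <- rbind(inner, outer)
  # mouth cone along +z (keeps rigid enclosure below the 96% cryptic bound)
  ang <- acos(pmin(1, pmax(-1, wall[, 3] / sqrt(rowSums(wall^2)))))
  wall <- wall[ang > 30 * pi / 180, , drop = FALSE]

  gate <- gate_residue(c(5.2, 0, 0), dir = c(-1, 0, 0), resno = 9998L)
  open_res <- gate_open_rotamer(gate$res, dist_f)
  mold_pts <- rbind(as.matrix(gate$res[, c("x", "y", "z")]),
                    as.matrix(open_res[, c("x", "y", "z")]))
  # mold the wall snugly around both gate conformations: push intruding wall
  # atoms out to 3.0 A (clash-free for the gate, but below the site-point
  # clearance, so the recess never holds site points of its own)
  for (pass in 1:3) {
    for (i in seq_len(nrow(mold_pts))) {
      d <- sqrt(colSums((t(wall) - mold_pts[i, ])^2))
      push <- which(d < 3.0 & d > 1e-6)
      for (j in push) {
        wall[j, ] <- mold_pts[i, ] + (wall[j, ] - mold_pts[i, ]) * 3.0 / d[j]
      }
    }
  }

  struct <- fixture_structure(wall, rep("C", nrow(wall)), gate = gate$res)
  # closed state: ball minus the chain's exclusion cylinder (radius ~3.1)
  a <- 3.1
  closed_est <- 4 / 3 * pi * (r^2 - a^2)^1.5
  truth <- list(closed_volume = closed_est, closed_volume_max = 100,
                open_volume = 4 / 3 * pi * r^3,
                site_exists = TRUE, n_sites = 1L,
                gate = list(chain = "A", resno = gate$res$resno[1],
                            open_chis = attr(open_res, "chis")))
  list(structure = struct, truth = truth)
}

# place a lysine gate: CA at `pos`, side chain extended along `dir`
gate_residue <- function(pos, dir, resno = 9999L) {
  tmpl <- aa_templates()
  tt <- tmpl[tmpl$resname == "LYS" & tmpl$element != "H", , drop = FALSE]
  xyz <- as.matrix(tt[, c("x", "y", "z")])
  ca <- xyz[match("CA", tt$atom), ]
  nz <- xyz[match("NZ", tt$atom), ]
  v <- nz - ca
  R <- align_z_to(dir) %*% t(align_z_to(v / sqrt(sum(v^2))))
  xyz <- sweep(sweep(xyz, 2, ca) %*% t(R), 2, pos, "+")
  res <- data.frame(
    type = "ATOM", eleno = seq_len(nrow(tt)), elety = tt$atom,
    resid = "LYS", chain = "A", resno = resno, insert = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], o = 1, b = 0,
    element = tt$element, is_het = FALSE, stringsAsFactors = FALSE)
  list(res = res)
}

# pick the open rotamer: the candidate whose side-chain atoms sit deepest in
# the wall zone (largest minimum clearance from the free region)
gate_open_rotamer <- function(res, dist_f) {
  side <- !toupper(res$elety) %in% c("N", "CA", "C", "O")
  best <- NULL; best_d <- -Inf; best_chis <- NULL
  for (cand in residue_rotamers(res)) {
    trial <- set_residue_chis(res, cand$chis)
    d <- min(dist_f(as.matrix(trial[side, c("x", "y", "z")])))
    if (d > best_d) { best_d <- d; best <- trial; best_chis <- cand$chis }
  }
  attr(best, "chis") <- best_chis
  best
}

lining_elements <- function(n_inner, n_outer, polar_fraction) {
  el <- rep("C", n_inner + n_outer)
  if (polar_fraction > 0) {
    k <- max(1, round(1 / polar_fraction))
    idx <- seq_len(n_inner)
    el[idx[idx %% k == 0]] <- "O"
  }
  el
}

# assemble wall atoms (plus optional gate residue) into a prepared structure
fixture_structure <- function(xyz, elements, gate = NULL) {
  n <- nrow(xyz)
  resno <- (seq_len(n) - 1) %/% 3 + 1
  within <- stats::ave(seq_len(n), resno, FUN = seq_along)
  atoms <- data.frame(
    type = "ATOM", eleno = seq_len(n),
    elety = paste0(elements, within),
    resid = "UNK", chain = "A", resno = resno, insert = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], o = 1, b = 0,
    element = elements, is_het = FALSE, stringsAsFactors = FALSE)
  if (!is.null(gate)) atoms <- rbind(atoms, gate)
  atoms$eleno <- seq_len(nrow(atoms))
  structure(list(
    atoms = atoms, source = "synthetic",
    retained_cofactors = character(), oversized_het = character(),
    removed_ligands = data.frame(resid = character(), chain = character(),
                                 resno = integer(), mw = numeric()),
    removed_ligand_atoms = NULL,
    n_residues_per_chain = c(A = length(unique(atoms$resno)))
  ), class = c("prepared_structure", "flexsite_structure"))
}

#' Write a fixture to disk
#'
#' @param fix result of [generate_fixture()]
#' @param pdb_path output PDB file
#' @param truth_path optional JSON file for the ground truth
#' @return `pdb_path`, invisibly
#' @export
write_fixture <- function(fix, pdb_path, truth_path = NULL) {
  write_structure(fix$structure, pdb_path)
  if (!is.null(truth_path))
    jsonlite::write_json(fix$truth, truth_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(pdb_path)
}
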