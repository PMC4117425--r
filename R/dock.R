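# Exhaustive rigid-body probe docking: translations on a lattice derived
# from the site points, a deterministic rotation set, and (for flexible
# probes) substituent-torsion conformers. Poses are scored by probe-receptor
# vdW energy plus a hydrophobic-contact bonus and a clash penalty; only
# net-favourable poses (energy below the admission ceiling) are admitted.

receptor_params <- function(s) {
  a <- heavy_atoms(s)
  pol <- atom_polarity(a$element, a$resid, a$elety)
  list(xyz = as.matrix(a[, c("x", "y", "z")]), rad = element_vdw(a$element),
       eps = element_eps(a$element), apolar = pol$apolar)
}

probe_params <- function(probe) {
  hv <- !probe$is_h
  list(rad = element_vdw(probe$element[hv]), eps = element_eps(probe$element[hv]),
       apolar = probe$element[hv] == "C", heavy = hv)
}

.pose_phobic_bonus <- 0.10   # per apolar contact pair, kcal/mol-scale
.pose_clash_penalty <- 5.0   # per hard clash
.pose_lj_cap <- 50.0         # repulsion cap per pair (clashes are prohibitive;
                             # induced-fit softness comes from side-chain
                             # trimming before the dock, not from the potential)

pose_energy_components <- function(pxyz, pp, rec, cfg) {
  sc <- cpp_contact_score(pxyz, pp$rad, pp$eps, pp$apolar,
                          rec$xyz, rec$rad, rec$eps, rec$apolar,
                          8.0, cfg$clash_distance, .pose_lj_cap)
  list(lj = sc[1], n_clash = sc[2], n_phob = sc[3],
       energy = sc[1] - .pose_phobic_bonus * sc[3] + .pose_clash_penalty * sc[2])
}

#' Dock a probe into a candidate site
#'
#' Rigid-body search over a translation lattice built from the site points
#' (subsampled at `translation_spacing`, clipped to the outer box around the
#' site-point centroid anchor), a deterministic rotation set, and torsion
#' conformers for flexible probes. Deterministic for fixed inputs.
#'
#' @param s receptor structure
#' @param site a `site` from [detect_sites()]
#' @param probe a `probe`
#' @param cfg [flex_config()]
#' @param max_poses number of admitted poses returned
#' @return list of poses sorted by ascending energy; each has `xyz` (all
#'   probe atoms), `energy`, `n_clash`, `centroid`; empty list when no pose
#'   beats the admission ceiling
#' @export
dock_probe <- function(s, site, probe, cfg = flex_config(), max_poses = 12) {
  anchor <- site$centroid
  lattice <- unique(round(sweep(site$points, 2, anchor) / cfg$translation_spacing))
  lattice <- lattice * cfg$translation_spacing
  keep <- apply(abs(lattice), 1, max) <= cfg$outer_box / 2
  lattice <- lattice[keep, , drop = FALSE]
  rec <- receptor_params(s)
  pp <- probe_params(probe)
  rots <- rotation_set(cfg$n_rot_axes, cfg$n_rot_spins)
  confs <- probe_conformers(probe, cfg)

  poses <- list()
  energies <- numeric()
  for (ci in seq_along(confs)) {
    all_xyz <- confs[[ci]]
    hxyz <- all_xyz[pp$heavy, , drop = FALSE]
    ctr <- colMeans(hxyz)
    hcent <- sweep(hxyz, 2, ctr)
    for (ri in seq_along(rots)) {
      rxyz <- hcent %*% t(rots[[ri]])
      for (ti in seq_len(nrow(lattice))) {
        pos <- anchor + lattice[ti, ]
        cand <- sweep(rxyz, 2, pos, "+")
        en <- pose_energy_components(cand, pp, rec, cfg)
        if (en$energy < cfg$admission_ceiling) {
          poses[[length(poses) + 1]] <- list(
            conformer = ci, rotation = ri, centroid = pos,
            energy = en$energy, n_clash = en$n_clash,
            xyz = sweep(sweep(all_xyz, 2, ctr) %*% t(rots[[ri]]), 2, pos, "+"),
            element = probe$element, is_h = probe$is_h, probe = probe$name)
          energies <- c(energies, en$energy)
        }
      }
    }
  }
  if (!length(poses)) return(list())
  poses <- poses[order(energies)]
  # diversity: successive poses must differ by at least 1 A in centroid
  kept <- list()
  for (p in poses) {
    if (length(kept) >= max_poses) break
    dup <- any(vapply(kept, function(q) sqrt(sum((q$centroid - p$centroid)^2)) < 1.0,
                      logical(1)))
    if (!dup) kept[[length(kept) + 1]] <- p
  }
  kept
}
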