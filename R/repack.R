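# Greedy side-chain rotamer repacking around a docked probe, with optional
# capped local backbone relaxation for residues whose best rotamer still
# clashes. Backbone heavy atoms never move more than the configured cap.

residue_keys <- function(atoms) paste(atoms$chain, atoms$resno, atoms$insert)

# Temporarily trim rotatable side chains near `points` to C-beta, the
# standard induced-fit docking device that lets a bulky probe enter a pocket
# whose side chains will be repacked afterwards.
trim_side_chains <- function(s, points, radius) {
  atoms <- s$atoms
  keys <- residue_keys(atoms)
  heavy <- atoms$element != "H" & !atoms$is_het
  drop <- rep(FALSE, nrow(atoms))
  for (k in unique(keys[heavy])) {
    idx <- which(keys == k & !atoms$is_het)
    res <- atoms[idx, , drop = FALSE]
    if (!toupper(res$resid[1]) %in% rotatable_residues()) next
    rxyz <- as.matrix(res[res$element != "H", c("x", "y", "z")])
    dmin <- min(apply(points, 1, function(p) min(sqrt(colSums((t(rxyz) - p)^2)))))
    if (dmin > radius) next
    side <- !toupper(res$elety) %in% c("N", "CA", "C", "O", "OXT", "CB")
    drop[idx[side]] <- TRUE
  }
  s$atoms <- atoms[!drop, , drop = FALSE]
  s
}

# clash + LJ energy of a residue's side chain against environment and probe
residue_energy <- function(res, env_xyz, env_rad, env_eps, env_apolar, cfg) {
  side <- which(!toupper(res$elety) %in% c("N", "CA", "C", "O", "OXT") &
                res$element != "H")
  if (!length(side)) return(list(energy = 0, n_clash = 0))
  sc <- cpp_contact_score(as.matrix(res[side, c("x", "y", "z")]),
                          element_vdw(res$element[side]),
                          element_eps(res$element[side]),
                          res$element[side] == "C",
                          env_xyz, env_rad, env_eps, env_apolar,
                          6.0, cfg$clash_distance)
  list(energy = sc[1] + 10 * sc[2], n_clash = sc[2])
}

#' Repack side chains around a probe pose
#'
#' Residues with any heavy atom within `repack_radius` of the probe are
#' reassigned the rotamer minimizing clash plus internal-preference energy,
#' greedily in order of worst initial clash, over two sweeps. If the best
#' rotamer of a residue still clashes and backbone relaxation is enabled, a
#' capped steepest-descent translation of the local window is applied; a
#' model with a remaining hard clash is discarded (returns `NULL`).
#'
#' @param s receptor structure
#' @param pose a pose from [dock_probe()]
#' @param cfg [flex_config()]
#' @return list with `structure` (receptor variant), `moved_residues`
#'   (data frame), `backbone_rmsd`; or `NULL` when an unresolvable clash
#'   remains
#' @export
repack_side_chains <- function(s, pose, cfg = flex_config()) {
  atoms <- s$atoms
  keys <- residue_keys(atoms)
  probe_xyz <- pose$xyz[!pose$is_h, , drop = FALSE]
  probe_rad <- element_vdw(pose$element[!pose$is_h])
  probe_eps <- element_eps(pose$element[!pose$is_h])
  probe_apolar <- pose$element[!pose$is_h] == "C"

  heavy <- atoms$element != "H" & !atoms$is_het
  cand_keys <- character()
  for (k in unique(keys[heavy])) {
    res <- atoms[keys == k & heavy, , drop = FALSE]
    if (!toupper(res$resid[1]) %in% rotatable_residues()) next
    rxyz <- as.matrix(res[, c("x", "y", "z")])
    dmin <- min(apply(probe_xyz, 1, function(p) min(sqrt(colSums((t(rxyz) - p)^2)))))
    if (dmin <= cfg$repack_radius) cand_keys <- c(cand_keys, k)
  }
  orig_backbone <- atoms[atoms$element != "H" &
                           toupper(atoms$elety) %in% c("N", "CA", "C", "O"), ]
  moved <- list()
  if (length(cand_keys)) {
    # order by worst initial clash against the probe
    clash0 <- vapply(cand_keys, function(k) {
      res <- atoms[keys == k, , drop = FALSE]
      env <- list(xyz = probe_xyz, rad = probe_rad, eps = probe_eps, ap = probe_apolar)
      residue_energy(res, env$xyz, env$rad, env$eps, env$ap, cfg)$n_clash
    }, numeric(1))
    cand_keys <- cand_keys[order(-clash0)]
    orig_chis <- lapply(cand_keys, function(k)
      residue_chi_values(atoms[keys == k, , drop = FALSE]))
    names(orig_chis) <- cand_keys
    for (sweep_i in 1:2) {
      for (k in cand_keys) {
        idx <- which(keys == k)
        res <- atoms[idx, , drop = FALSE]
        other <- atoms[-idx, , drop = FALSE]
        other <- other[other$element != "H", , drop = FALSE]
        env_xyz <- rbind(as.matrix(other[, c("x", "y", "z")]), probe_xyz)
        env_rad <- c(element_vdw(other$element), probe_rad)
        env_eps <- c(element_eps(other$element), probe_eps)
        env_ap <- c(other$element == "C", probe_apolar)
        cur_chis <- residue_chi_values(res)
        cands <- c(list(list(chis = cur_chis, penalty = 0)),
                   residue_rotamers(res))
        best <- NULL; best_en <- Inf
        for (cand in cands) {
          trial <- set_residue_chis(res, cand$chis)
          en <- residue_energy(trial, env_xyz, env_rad, env_eps, env_ap, cfg)
          tot <- en$energy + cand$penalty
          if (tot < best_en) { best_en <- tot; best <- list(res = trial, en = en, chis = cand$chis) }
        }
        # refine around the best with +/-30 degree sub-samples
        for (cand in rotamer_subsample(best$chis)) {
          trial <- set_residue_chis(res, cand$chis)
          en <- residue_energy(trial, env_xyz, env_rad, env_eps, env_ap, cfg)
          tot <- en$energy + cand$penalty
          if (tot < best_en) { best_en <- tot; best <- list(res = trial, en = en, chis = cand$chis) }
        }
        if (best$en$n_clash > 0 && cfg$backbone_relax) {
          best <- relax_window(best, atoms, idx, probe_xyz, probe_rad, cfg,
                               env_xyz, env_rad, env_eps, env_ap)
        }
        if (sweep_i == 2 && best$en$n_clash > 0) return(NULL)
        atoms[idx, c("x", "y", "z")] <- best$res[, c("x", "y", "z")]
      }
    }
    for (k in cand_keys) {
      res <- atoms[keys == k, , drop = FALSE]
      delta <- (residue_chi_values(res) - orig_chis[[k]]) %% (2 * pi)
      delta <- pmin(delta, 2 * pi - delta)
      chi_delta <- suppressWarnings(max(abs(delta), na.rm = TRUE))
      if (is.finite(chi_delta) && chi_delta > 0.02)
        moved[[k]] <- data.frame(chain = res$chain[1], resno = res$resno[1],
                                 resid = res$resid[1],
                                 max_chi_change_deg = round(chi_delta * 180 / pi, 1))
    }
  }
  out <- s
  out$atoms <- atoms
  new_backbone <- atoms[atoms$element != "H" &
                          toupper(atoms$elety) %in% c("N", "CA", "C", "O"), ]
  rmsd <- if (nrow(orig_backbone))
    sqrt(mean(rowSums((as.matrix(orig_backbone[, c("x", "y", "z")]) -
                         as.matrix(new_backbone[, c("x", "y", "z")]))^2))) else 0
  list(structure = out,
       moved_residues = if (length(moved)) do.call(rbind, moved) else
         data.frame(chain = character(), resno = integer(), resid = character(),
                    max_chi_change_deg = numeric()),
       backbone_rmsd = rmsd)
}

# Capped steepest-descent rigid translation of a residue (backbone included)
# whose best rotamer still clashes with the probe: a local backbone
# movement bounded by the backbone cap.
relax_window <- function(best, atoms, idx, probe_xyz, probe_rad, cfg,
                         env_xyz, env_rad, env_eps, env_ap) {
  res <- best$res
  res_xyz <- as.matrix(res[, c("x", "y", "z")])
  total_shift <- c(0, 0, 0)
  for (step in seq_len(50)) {
    # net repulsion direction away from overlapping probe atoms
    grad <- c(0, 0, 0); overlaps <- 0
    for (i in seq_len(nrow(res_xyz))) {
      d <- sqrt(colSums((t(probe_xyz) - res_xyz[i, ])^2))
      touch <- element_vdw(res$element[i]) + probe_rad
      ov <- which(d < touch - cfg$clash_distance)
      for (j in ov) {
        v <- res_xyz[i, ] - probe_xyz[j, ]
        nv <- sqrt(sum(v^2))
        if (nv > 1e-6) { grad <- grad + v / nv; overlaps <- overlaps + 1 }
      }
    }
    if (overlaps == 0) break
    grad <- grad / sqrt(sum(grad^2)) * 0.1
    if (sqrt(sum((total_shift + grad)^2)) > cfg$backbone_cap) break
    total_shift <- total_shift + grad
    res_xyz <- sweep(res_xyz, 2, grad, "+")
  }
  if (sqrt(sum(total_shift^2)) > 1e-9) {
    res[, c("x", "y", "z")] <- res_xyz
    en <- residue_energy(res, env_xyz, env_rad, env_eps, env_ap, cfg)
    best <- list(res = res, en = en, chis = best$chis)
  }
  best
}
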