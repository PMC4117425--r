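# Two-stage induced-fit cycle: dock naphthalene, repack, then dock the
# tetra-substituted naphthalene (TSN) into the opened pocket, repack again,
# and re-detect/re-score the site on the top models.

#' Two-stage induced-fit flexibility cycle for one site
#'
#' Stage one docks rigid naphthalene and keeps the best
#' `n_naph_poses_kept` poses, repacking nearby side chains for each. Stage
#' two docks TSN into each stage-one variant (probe removed) and repacks
#' again. When TSN admits no pose for a variant, the stage-one variant
#' itself is retained as a model. The `n_models_scored` top models by pose
#' energy are re-scored by re-detecting the site in a box around the
#' site-point anchor.
#'
#' @param s `prepared_structure`
#' @param site rigid-detection `site` (must have passed the rigid gate)
#' @param cfg [flex_config()]
#' @param det_cfg [detection_config()]
#' @param weights [score_weights()]
#' @return list of `flex_model`: `structure`, `pose`, `pose_energy`,
#'   `moved_residues`, `backbone_rmsd`, `stage`, and `rescored`
#'   (site + descriptors); empty list when stage one returns no pose
#' @export
induced_fit_cycle <- function(s, site, cfg = flex_config(),
                              det_cfg = detection_config(),
                              weights = score_weights()) {
  naph <- load_probe("naphthalene")
  tsn <- load_probe("tsn")
  anchor <- site$centroid

  # dock against a side-chain-trimmed receptor: repackable residues near the
  # site are reduced to C-beta so the probe can enter pockets their current
  # rotamers occlude; repacking then restores and resolves them
  s_trim <- trim_side_chains(s, site$points, cfg$repack_radius)
  stage1 <- dock_probe(s_trim, site, naph, cfg)
  if (!length(stage1)) return(list())
  stage1 <- stage1[seq_len(min(cfg$n_naph_poses_kept, length(stage1)))]

  variants <- list()
  for (pose in stage1) {
    rp <- repack_side_chains(s, pose, cfg)
    if (!is.null(rp)) variants[[length(variants) + 1]] <-
        list(structure = rp$structure, naph_pose = pose,
             moved = rp$moved_residues, rmsd = rp$backbone_rmsd)
  }
  if (!length(variants)) return(list())

  per_variant <- ceiling(cfg$min_models_generated / length(variants))
  models <- list()
  for (v in variants) {
    # dock TSN against a side-chain-trimmed receptor (repacking restores and
    # resolves the trimmed residues afterwards)
    trim_pts <- rbind(site$points, v$naph_pose$xyz[!v$naph_pose$is_h, , drop = FALSE])
    trimmed <- trim_side_chains(v$structure, trim_pts, cfg$repack_radius + 3)
    tposes <- dock_probe(trimmed, site, tsn, cfg, max_poses = per_variant)
    if (length(tposes)) {
      for (pose in tposes) {
        rp <- repack_side_chains(v$structure, pose, cfg)
        if (is.null(rp)) next
        models[[length(models) + 1]] <- list(
          structure = rp$structure, pose = pose, pose_energy = pose$energy,
          moved_residues = unique(rbind(v$moved, rp$moved_residues)),
          backbone_rmsd = rp$backbone_rmsd, stage = "tsn")
      }
    } else {
      models[[length(models) + 1]] <- list(
        structure = v$structure, pose = v$naph_pose,
        pose_energy = v$naph_pose$energy, moved_residues = v$moved,
        backbone_rmsd = v$rmsd, stage = "naphthalene")
    }
  }
  if (!length(models)) return(list())
  models <- models[order(vapply(models, function(m) m$pose_energy, numeric(1)))]
  models <- models[seq_len(min(cfg$n_models_scored, length(models)))]

  lapply(models, function(m) {
    m$rescored <- rescore_site(m$structure, anchor, cfg, det_cfg, weights)
    class(m) <- "flex_model"
    m
  })
}

# Re-detect the site near the anchor on a receptor variant and return the
# nearest detected site (with descriptors), or NULL if none is found.
rescore_site <- function(s, anchor, cfg, det_cfg, weights) {
  bounds <- rbind(anchor - cfg$rescore_halfbox, anchor + cfg$rescore_halfbox)
  det <- detect_sites(s, det_cfg, weights, bounds = bounds)
  if (!length(det$sites)) return(NULL)
  d <- vapply(det$sites, function(x) sqrt(sum((x$centroid - anchor)^2)), numeric(1))
  det$sites[[which.min(d)]]
}

#' Aggregate flexible models into the reported flexible result
#'
#' Returns the maximum rescored Dscore+ across models together with the
#' volume of that same model; ties on the reported score go to the larger
#' volume. All models stay available in the full report.
#'
#' @param models list of `flex_model` from [induced_fit_cycle()]
#' @return list `dscore_plus_flex`, `volume_flex`, `enclosure_flex`,
#'   `best_model` (index); or NULL when no model was rescored
#' @export
flexible_result <- function(models) {
  scored <- Filter(function(m) !is.null(m$rescored), models)
  if (!length(scored)) return(NULL)
  sc <- vapply(scored, function(m) m$rescored$descriptors$dscore_plus_reported, numeric(1))
  vol <- vapply(scored, function(m) m$rescored$volume, numeric(1))
  best <- order(-sc, -vol)[1]
  list(dscore_plus_flex = sc[best], volume_flex = vol[best],
       enclosure_flex = scored[[best]]$rescored$descriptors$e,
       best_model = which(vapply(models, identical, logical(1), scored[[best]]))[1])
}

#' Write flexible models as a multi-model PDB plus per-model JSON
#'
#' @param models list of `flex_model`
#' @param stem output path stem (`.pdb` / `.json` appended)
#' @return `stem`, invisibly
#' @export
write_models <- function(models, stem) {
  con <- file(paste0(stem, ".pdb"), "wt")
  for (i in seq_along(models)) {
    writeLines(sprintf("MODEL     %4d", i), con)
    tmp <- tempfile(fileext = ".pdb")
    write_structure(models[[i]]$structure, tmp)
    writeLines(setdiff(readLines(tmp), "END"), con)
    unlink(tmp)
    writeLines("ENDMDL", con)
  }
  close(con)
  jsonlite::write_json(lapply(seq_along(models), function(i) {
    m <- models[[i]]
    list(model = i, pose_energy = m$pose_energy, stage = m$stage,
         backbone_rmsd = m$backbone_rmsd,
         moved_residues = m$moved_residues,
         rescored = if (!is.null(m$rescored)) unclass(m$rescored$descriptors))
  }), paste0(stem, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(stem)
}
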