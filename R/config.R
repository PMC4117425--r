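# Configuration objects. Defaults follow the published non-default pocket
# detection parameter set (maxdist = 10, enclosure = 0.4, maxvdw = 1.0,
# dthresh = 5.0, mingroup = 7, nthresh = 7, grid = 0.35, modphobic = 0), the
# induced-fit settings (25 A outer box, two naphthalene poses, four scored
# models) and the decision gates (Dscore+ > 1.3 rigid, >= 1.7 flexible,
# drug-like volume 160-800 A^3).

#' Pocket detection configuration
#'
#' @param grid_spacing grid spacing in Angstrom
#' @param maxdist maximum ray distance for the enclosure fraction (A)
#' @param enclosure_min minimum enclosure fraction for a site point
#' @param maxvdw minimum magnitude of (negative) probe vdW energy, kcal/mol
#' @param dthresh site joining distance: clusters closer than this merge (A)
#' @param neighbor_radius support-filter neighbour radius (A, sqrt(d2thresh))
#' @param nthresh minimum number of neighbouring site points for support
#' @param mingroup minimum points per site
#' @param modphobic hydrophobic potential mode; 0 = raw, no openness modulation
#' @param n_rays number of enclosure ray directions
#' @param max_sites number of top-ranked sites returned
#' @param vdw_cutoff probe energy summation cutoff (A)
#' @param polar_cutoff phobic/philic kernel cutoff (A)
#' @param margin grid margin beyond the receptor bounding box (A)
#' @param max_points memory budget: maximum number of grid points
#' @param score_count_spacing reference spacing (A) for the score-equivalent
#'   site-point count (see [site_descriptors()])
#' @return object of class `detection_config`
#' @export
detection_config <- function(grid_spacing = 0.35, maxdist = 10,
                             enclosure_min = 0.4, maxvdw = 1.0,
                             dthresh = 5.0, neighbor_radius = 1.76,
                             nthresh = 7, mingroup = 7, modphobic = 0,
                             n_rays = 110, max_sites = 5, vdw_cutoff = 8,
                             polar_cutoff = 6, margin = 8,
                             max_points = 8e6, score_count_spacing = 1.4) {
  stopifnot(grid_spacing > 0, maxdist > 0, dthresh > 0, neighbor_radius > 0,
            nthresh >= 1, mingroup >= 1, enclosure_min >= 0, enclosure_min <= 1,
            maxvdw > 0, n_rays >= 1, max_sites >= 1)
  structure(as.list(environment()), class = "detection_config")
}

#' Induced-fit flexibility configuration
#'
#' @param outer_box docking search box edge (A); the probe centroid stays
#'   within this box centred on the binding-site anchor
#' @param n_naph_poses_kept naphthalene poses carried to stage two
#' @param n_models_scored models re-scored after stage two
#' @param min_models_generated model count the stage-two search aims for
#' @param clash_distance tolerated vdW overlap before a hard clash (A)
#' @param repack_radius residues within this distance of the probe repack (A)
#' @param admission_ceiling poses with energy above this are rejected
#' @param translation_spacing docking translation lattice spacing (A)
#' @param n_rot_axes,n_rot_spins rigid rotation set size (axes x spins)
#' @param torsion_step substituent torsion sampling step (degrees)
#' @param max_conformers cap on flexible-probe conformers docked
#' @param backbone_relax allow capped local backbone relaxation
#' @param backbone_cap maximum backbone atom displacement (A)
#' @param rescore_halfbox half-edge of the re-detection box around the anchor (A)
#' @param seed integer seed recorded with results
#' @return object of class `flex_config`
#' @export
flex_config <- function(outer_box = 25, n_naph_poses_kept = 2,
                        n_models_scored = 4, min_models_generated = 10,
                        clash_distance = 0.6, repack_radius = 5,
                        admission_ceiling = 0, translation_spacing = 1.0,
                        n_rot_axes = 12, n_rot_spins = 6, torsion_step = 60,
                        max_conformers = 6, backbone_relax = TRUE,
                        backbone_cap = 1.5, rescore_halfbox = 12, seed = 0L) {
  stopifnot(outer_box > 0, n_naph_poses_kept >= 1, n_models_scored >= 1)
  structure(as.list(environment()), class = "flex_config")
}

#' Druggability decision configuration
#'
#' @param rigid_gate rigid Dscore+ gate (strict greater-than)
#' @param flexible_gate flexible Dscore+ gate (greater-or-equal)
#' @param druglike_volume inclusive drug-like volume interval (A^3)
#' @param cryptic_max_initial_volume rigid volume ceiling for cryptic pockets (A^3)
#' @param cryptic_max_enclosure rigid enclosure ceiling for cryptic pockets (percent)
#' @param cryptic_enclosure_strict use strict `<` for the enclosure ceiling
#' @param min_protein_residues minimum chain length for cryptic calls
#' @param interface_contact_distance TSN-partner-chain contact distance (A)
#' @param ligand_mw_max ligand definition: molecular weight ceiling (Da)
#' @return object of class `decision_config`
#' @export
decision_config <- function(rigid_gate = 1.3, flexible_gate = 1.7,
                            druglike_volume = c(160, 800),
                            cryptic_max_initial_volume = 100,
                            cryptic_max_enclosure = 96,
                            cryptic_enclosure_strict = FALSE,
                            min_protein_residues = 100,
                            interface_contact_distance = 2.0,
                            ligand_mw_max = 1000) {
  stopifnot(length(druglike_volume) == 2, druglike_volume[1] < druglike_volume[2])
  structure(as.list(environment()), class = "decision_config")
}

#' Dscore weights
#'
#' Coefficients of the weighted-sum druggability score
#' `Dscore = w_size * sqrt(n) + w_enclosure * e - w_philic * min(p, philic_cap)`.
#' Defaults are the published coefficients of the original druggability
#' score; they are open configuration constants of this implementation.
#'
#' @param w_size coefficient on sqrt(site-point count)
#' @param w_enclosure coefficient on the enclosure score
#' @param w_philic magnitude of the (negative) hydrophilic contribution
#' @param philic_cap cap applied to the hydrophilic score before weighting
#' @return object of class `score_weights`
#' @export
score_weights <- function(w_size = 0.094, w_enclosure = 0.60,
                          w_philic = 0.324, philic_cap = 1.0) {
  stopifnot(w_size > 0, w_enclosure > 0, w_philic > 0, philic_cap > 0)
  structure(as.list(environment()), class = "score_weights")
}

#' Full run configuration
#'
#' @param detection,flex,decision,weights component configurations
#' @param seed integer seed applied to every stochastic stage
#' @param timeout per-structure wall-time budget (seconds)
#' @return object of class `run_config`
#' @export
run_config <- function(detection = detection_config(), flex = flex_config(),
                       decision = decision_config(), weights = score_weights(),
                       seed = 0L, timeout = 3600) {
  flex$seed <- as.integer(seed)
  structure(list(detection = detection, flex = flex, decision = decision,
                 weights = weights, seed = as.integer(seed), timeout = timeout),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' File values overlay the defaults; unknown keys are an error naming the
#' key. Top-level sections are `detection`, `flex`, `decision`, `weights`,
#' plus scalar `seed` and `timeout`.
#'
#' @param path YAML file; an empty file yields all defaults
#' @return `run_config`
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- c("detection", "flex", "decision", "weights", "seed", "timeout")
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key: ", paste(bad, collapse = ", "))
  ctor <- list(detection = detection_config, flex = flex_config,
               decision = decision_config, weights = score_weights)
  parts <- lapply(names(ctor), function(nm) {
    sub <- vals[[nm]] %||% list()
    allowed <- names(formals(ctor[[nm]]))
    bad <- setdiff(names(sub), allowed)
    if (length(bad)) stop("unknown config key: ", nm, ".", paste(bad, collapse = ", "))
    do.call(ctor[[nm]], sub)
  })
  names(parts) <- names(ctor)
  run_config(detection = parts$detection, flex = parts$flex,
             decision = parts$decision, weights = parts$weights,
             seed = vals$seed %||% 0L, timeout = vals$timeout %||% 3600)
}

#' @export
print.run_config <- function(x, ...) {
  cat("flexsite run configuration\n")
  for (section in c("detection", "flex", "decision", "weights")) {
    cat("[", section, "]\n", sep = "")
    vals <- x[[section]]
    for (nm in names(vals)) {
      cat("  ", nm, " = ", paste(format(vals[[nm]]), collapse = ", "), "\n", sep = "")
    }
  }
  cat("seed =", x$seed, " timeout =", x$timeout, "s\n")
  invisible(x)
}
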