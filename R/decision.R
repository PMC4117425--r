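# Druggability gates and classification: rigid gate (Dscore+ > 1.3),
# flexible gate (Dscore+ >= 1.7), drug-like volume 160-800 A^3 (inclusive),
# cryptic-pocket rule (rigid volume <= 100 A^3, rigid enclosure <= 96%,
# chain of at least 100 residues), interface annotation, and the
# per-structure pipeline driver. Gates are applied to one-decimal reported
# scores, matching the reporting convention.

#' Rigid druggability gate
#'
#' @param dscore_plus_reported one-decimal rigid Dscore+
#' @param cfg [decision_config()]
#' @return TRUE when the site advances to flexibility modeling (strict `>`)
#' @export
rigid_gate <- function(dscore_plus_reported, cfg = decision_config()) {
  dscore_plus_reported > cfg$rigid_gate
}

in_druglike_volume <- function(v, cfg) {
  v >= cfg$druglike_volume[1] & v <= cfg$druglike_volume[2]
}

#' Classify a site into a druggability record
#'
#' @param structure_id identifier for reporting
#' @param site_id site rank/id
#' @param rigid list with `dscore_plus` (reported), `V`, `e` (fraction or
#'   percent, see `e_percent`)
#' @param flexible list with `dscore_plus` (reported) and `V`, or NULL when
#'   flexibility was not applied / returned nothing
#' @param chain_residues residue count of the (largest) protein chain
#' @param cfg [decision_config()]
#' @return a `druggability_record` with label in `druggable_rigid`,
#'   `druggable_flexible`, `cryptic_druggable`, `difficult`, `not_advanced`,
#'   `oversized_site`, plus `rigid_druggable` flag and interface flags
#' @export
classify <- function(structure_id, site_id, rigid, flexible = NULL,
                     chain_residues = NA_integer_, cfg = decision_config()) {
  if (is.null(rigid) && !is.null(flexible))
    stop("inconsistent inputs: flexible values without rigid values")
  e_pct <- if (!is.null(rigid$e) && !is.na(rigid$e) && rigid$e <= 1)
    rigid$e * 100 else rigid$e
  rigid_druggable <- rigid_gate(rigid$dscore_plus, cfg) &&
    in_druglike_volume(rigid$V, cfg)
  flex_pass <- !is.null(flexible) &&
    flexible$dscore_plus >= cfg$flexible_gate &&
    in_druglike_volume(flexible$V, cfg)
  enc_ok <- if (is.null(e_pct) || is.na(e_pct)) FALSE
    else if (cfg$cryptic_enclosure_strict) e_pct < cfg$cryptic_max_enclosure
    else e_pct <= cfg$cryptic_max_enclosure
  cryptic <- flex_pass &&
    rigid$V <= cfg$cryptic_max_initial_volume &&
    enc_ok &&
    !is.na(chain_residues) && chain_residues >= cfg$min_protein_residues

  label <-
    if (rigid$V > cfg$druglike_volume[2]) "oversized_site"
    else if (!rigid_gate(rigid$dscore_plus, cfg)) "not_advanced"
    else if (cryptic) "cryptic_druggable"
    else if (flex_pass) "druggable_flexible"
    else if (is.null(flexible) && rigid_druggable) "druggable_rigid"
    else "difficult"

  structure(list(
    structure_id = structure_id, site_id = site_id,
    rigid = list(dscore_plus = rigid$dscore_plus, V = rigid$V, e = e_pct),
    flexible = if (!is.null(flexible))
      list(dscore_plus = flexible$dscore_plus, V = flexible$V),
    label = label, rigid_druggable = rigid_druggable,
    chain_residues = chain_residues,
    ppi_interface = FALSE, ligand_pocket = FALSE, notes = character()
  ), class = "druggability_record")
}

#' Annotate interface character of a record
#'
#' Marks a protein-protein interface pocket when any atom of the docked TSN
#' pose (hydrogens included) lies within the contact distance of an atom of
#' another protein chain, and a ligand pocket when the site's occupied grid
#' cells overlap the vdW envelope of a removed ligand by more than 0 A^3.
#'
#' @param record a `druggability_record`
#' @param s `prepared_structure` (carries the removed-ligand registry)
#' @param site the rigid `site`
#' @param tsn_pose TSN pose (all atoms) or NULL
#' @param site_chain chain id owning the site (excluded from partner search)
#' @param cfg [decision_config()]
#' @param det_cfg [detection_config()]
#' @return the record with `ppi_interface` and `ligand_pocket` set
#' @export
annotate_interfaces <- function(record, s, site, tsn_pose = NULL,
                                site_chain = NULL, cfg = decision_config(),
                                det_cfg = detection_config()) {
  atoms <- s$atoms
  if (!is.null(tsn_pose)) {
    prot <- atoms[!atoms$is_het, , drop = FALSE]
    if (is.null(site_chain)) {
      # chain nearest to the site centroid owns the site
      d <- sqrt((prot$x - site$centroid[1])^2 + (prot$y - site$centroid[2])^2 +
                  (prot$z - site$centroid[3])^2)
      site_chain <- prot$chain[which.min(d)]
    }
    partner <- prot[prot$chain != site_chain, , drop = FALSE]
    if (nrow(partner)) {
      pxyz <- as.matrix(partner[, c("x", "y", "z")])
      hit <- any(apply(tsn_pose$xyz, 1, function(p)
        min(sqrt(colSums((t(pxyz) - p)^2))) <= cfg$interface_contact_distance))
      record$ppi_interface <- isTRUE(hit)
    }
  }
  lig <- s$removed_ligand_atoms
  if (!is.null(lig) && nrow(lig)) {
    lxyz <- as.matrix(lig[lig$element != "H", c("x", "y", "z")])
    lrad <- element_vdw(lig$element[lig$element != "H"])
    inside <- cpp_points_inside(site$points, lxyz, lrad)
    overlap <- sum(inside) * det_cfg$grid_spacing^3
    record$ligand_pocket <- overlap > 0
    record$ligand_overlap_A3 <- overlap
  }
  record
}

#' Run the full druggability pipeline on one structure
#'
#' Prepare, detect the top sites, score rigidly, run the induced-fit cycle
#' for sites passing the rigid gate, classify, and annotate interfaces.
#'
#' @param path PDB file
#' @param config [run_config()]
#' @param assembly_mode,chain see [read_structure()]
#' @return list of `druggability_record`, one per detected site, with the
#'   per-site details attached as attributes `sites` and `models`
#' @export
run_pipeline <- function(path, config = run_config(),
                         assembly_mode = "as-deposited", chain = NULL) {
  t0 <- proc.time()[["elapsed"]]
  raw <- read_structure(path, assembly_mode, chain)
  prep <- if (inherits(raw, "prepared_structure")) raw else
    prepare(raw, ligand_mw_max = config$decision$ligand_mw_max)
  det <- detect_sites(prep, config$detection, config$weights)
  structure_id <- tools::file_path_sans_ext(basename(path))
  chain_res <- if (length(prep$n_residues_per_chain))
    max(prep$n_residues_per_chain) else NA_integer_

  records <- list()
  models_all <- list()
  for (site in det$sites) {
    d <- site$descriptors
    rigid <- list(dscore_plus = d$dscore_plus_reported, V = d$V, e = d$e)
    flexible <- NULL
    tsn_pose <- NULL
    models <- list()
    if (rigid_gate(d$dscore_plus_reported, config$decision) &&
        d$V <= config$decision$druglike_volume[2]) {
      models <- induced_fit_cycle(prep, site, config$flex,
                                  config$detection, config$weights)
      fr <- flexible_result(models)
      if (!is.null(fr)) {
        flexible <- list(dscore_plus = fr$dscore_plus_flex, V = fr$volume_flex)
        best <- models[[fr$best_model]]
        if (identical(best$stage, "tsn")) tsn_pose <- best$pose
      }
    }
    rec <- classify(structure_id, site$site_id, rigid, flexible,
                    chain_res, config$decision)
    rec <- annotate_interfaces(rec, prep, site, tsn_pose,
                               cfg = config$decision,
                               det_cfg = config$detection)
    records[[length(records) + 1]] <- rec
    models_all[[length(models_all) + 1]] <- models
  }
  attr(records, "sites") <- det$sites
  attr(records, "models") <- models_all
  attr(records, "elapsed") <- proc.time()[["elapsed"]] - t0
  records
}

#' Run the pipeline over a list of structures
#'
#' @param paths character vector of PDB files
#' @param config [run_config()]
#' @return named list of per-structure record lists; failures are recorded
#'   as condition messages rather than aborting the batch
#' @export
run_batch <- function(paths, config = run_config()) {
  out <- lapply(paths, function(p) {
    tryCatch(run_pipeline(p, config),
             error = function(e) structure(list(error = conditionMessage(e)),
                                           class = "flexsite_failure"))
  })
  names(out) <- vapply(paths, function(p) tools::file_path_sans_ext(basename(p)), "")
  out
}

#' Summarize records as a data frame
#'
#' @param records list of `druggability_record` (or list of such lists)
#' @return data frame, one row per record
#' @export
records_table <- function(records) {
  if (length(records) && inherits(records[[1]], "druggability_record"))
    records <- list(records)
  rows <- list()
  for (rs in records) {
    if (inherits(rs, "flexsite_failure")) next
    for (r in rs) {
      rows[[length(rows) + 1]] <- data.frame(
        structure_id = r$structure_id, site_id = r$site_id,
        rigid_dscore_plus = r$rigid$dscore_plus,
        rigid_volume = round(r$rigid$V, 1),
        rigid_enclosure_pct = round(r$rigid$e, 1),
        flex_dscore_plus = if (!is.null(r$flexible)) r$flexible$dscore_plus else NA,
        flex_volume = if (!is.null(r$flexible)) round(r$flexible$V, 1) else NA,
        label = r$label, rigid_druggable = r$rigid_druggable,
        ppi_interface = r$ppi_interface, ligand_pocket = r$ligand_pocket,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame())
  do.call(rbind, rows)
}

#' @export
print.druggability_record <- function(x, ...) {
  cat(x$structure_id, "site", x$site_id, ":", x$label,
      sprintf("(rigid %.1f / %.0f A^3", x$rigid$dscore_plus, x$rigid$V))
  if (!is.null(x$flexible))
    cat(sprintf("; flexible %.1f / %.0f A^3", x$flexible$dscore_plus, x$flexible$V))
  cat(")\n")
  invisible(x)
}
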