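# Reading PDB structures, preparation (water/ligand removal with a cofactor
# keep-list, polar hydrogen placement, side-chain completion) and writing of
# prepared structures and site-point pseudo-atom files. Parsing and writing
# of the PDB format itself is delegated to bio3d.

#' Default cofactor keep-list
#'
#' Het group codes retained during preparation regardless of molecular
#' weight: heme variants plus zinc and magnesium.
#'
#' @return character vector of 3-letter het codes
#' @export
default_keep_list <- function() {
  c("HEM", "MHM", "HEV", "VER", "SRM", "HEO", "HEB", "HEC",
    "HDM", "HDD", "DDH", "ZN", "MG")
}

.water_codes <- c("HOH", "WAT", "DOD", "H2O", "TIP")

guess_element <- function(elety, elesy = NULL) {
  out <- toupper(trimws(elesy %||% ""))
  miss <- is.na(out) | out == ""
  if (any(miss)) {
    nm <- gsub("[^A-Za-z]", "", elety[miss])
    two <- toupper(substr(nm, 1, 2))
    one <- toupper(substr(nm, 1, 1))
    guess <- ifelse(two %in% c("ZN", "MG", "FE", "MN", "CU", "NA", "CL",
                               "BR", "SE", "NI", "CO"), two, one)
    # names like "CA"/"CB"/"CD" inside amino acids are carbons, not Ca/Cd
    out[miss] <- guess
  }
  out
}

#' Read a protein structure in PDB format
#'
#' Reads ATOM/HETATM records (first MODEL when several are present). In
#' monomer mode only the requested protein chain is returned, together with
#' the het entities assigned to it by closest protein heavy atom (ties broken
#' by chain-id order).
#'
#' @param path PDB-format file
#' @param assembly_mode `"as-deposited"` or `"monomer"`
#' @param chain chain id, required for monomer mode
#' @return a `flexsite_structure`: list with an `atoms` data frame
#'   (type, elety, resid, chain, resno, x, y, z, o, element, is_het)
#' @export
read_structure <- function(path, assembly_mode = c("as-deposited", "monomer"),
                           chain = NULL) {
  assembly_mode <- match.arg(assembly_mode)
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path, multi = FALSE)),
                  error = function(e) stop("cannot parse PDB file '", path,
                                           "': ", conditionMessage(e)))
  at <- pdb$atom
  at <- at[at$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  atoms <- data.frame(
    type = at$type, eleno = at$eleno, elety = trimws(at$elety),
    resid = trimws(at$resid), chain = ifelse(is.na(at$chain), "A", at$chain),
    resno = at$resno, insert = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    o = ifelse(is.na(at$o), 1, at$o), b = ifelse(is.na(at$b), 0, at$b),
    element = guess_element(trimws(at$elety), at$elesy),
    stringsAsFactors = FALSE
  )
  atoms$is_het <- atoms$type == "HETATM"
  s <- structure(list(atoms = atoms, source = path), class = "flexsite_structure")
  check_not_calpha_only(s)
  if (assembly_mode == "monomer") {
    if (is.null(chain)) stop("monomer mode requires a chain id")
    if (!chain %in% atoms$chain[!atoms$is_het])
      stop("chain '", chain, "' not found in ", path)
    s <- select_monomer(s, chain)
  }
  s
}

check_not_calpha_only <- function(s) {
  prot <- s$atoms[!s$atoms$is_het, , drop = FALSE]
  if (nrow(prot) == 0) return(invisible(s))
  key <- paste(prot$chain, prot$resno, prot$insert)
  ca_only <- vapply(split(prot$elety, key),
                    function(a) all(toupper(a) %in% c("CA")), logical(1))
  if (mean(ca_only) > 0.5)
    stop(structure(class = c("flexsite_calpha_error", "error", "condition"),
                   list(message = paste0("structure contains only C-alpha atoms for ",
                                         round(100 * mean(ca_only)), "% of residues"),
                        call = NULL)))
  invisible(s)
}

# het entity key: one residue record of HETATM atoms
het_entity_key <- function(atoms) paste(atoms$chain, atoms$resno, atoms$resid, atoms$insert)

select_monomer <- function(s, chain) {
  atoms <- s$atoms
  prot <- atoms[!atoms$is_het, , drop = FALSE]
  keep_prot <- !atoms$is_het & atoms$chain == chain
  het <- atoms[atoms$is_het, , drop = FALSE]
  keep_het <- rep(FALSE, nrow(atoms))
  if (nrow(het) > 0) {
    pxyz <- as.matrix(prot[prot$element != "H", c("x", "y", "z")])
    pchain <- prot$chain[prot$element != "H"]
    chains_in_order <- sort(unique(pchain))
    for (k in unique(het_entity_key(het))) {
      e <- het[het_entity_key(het) == k, , drop = FALSE]
      exyz <- as.matrix(e[, c("x", "y", "z")])
      # nearest protein heavy atom per chain
      best <- vapply(chains_in_order, function(ch) {
        sub <- pxyz[pchain == ch, , drop = FALSE]
        min(vapply(seq_len(nrow(exyz)), function(i) {
          min(sqrt(colSums((t(sub) - exyz[i, ])^2)))
        }, numeric(1)))
      }, numeric(1))
      owner <- chains_in_order[which.min(best)]  # which.min = first on ties
      if (owner == chain)
        keep_het <- keep_het | (atoms$is_het & het_entity_key(atoms) == k)
    }
  }
  s$atoms <- atoms[keep_prot | keep_het, , drop = FALSE]
  s
}

# Molecular weight of a het entity from atomic composition; implicit
# hydrogens estimated by valence minus observed covalent neighbours.
het_entity_mw <- function(e) {
  heavy <- e[e$element != "H", , drop = FALSE]
  xyz <- as.matrix(heavy[, c("x", "y", "z")])
  mw <- sum(element_mass(heavy$element))
  val <- c(C = 4, N = 3, O = 2, S = 2, P = 5)
  nH <- 0
  for (i in seq_len(nrow(heavy))) {
    v <- val[heavy$element[i]]
    if (is.na(v)) next
    d <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    nb <- sum(d > 1e-6 & d < 1.85)
    nH <- nH + max(0, v - nb)
  }
  # aromatic/sp2 carbons carry fewer hydrogens than the sp3 valence estimate;
  # scale the estimate down to a typical organic H load
  mw + 1.008 * nH * 0.75
}

#' Prepare a structure for pocket detection
#'
#' Removes waters; removes het entities with molecular weight at or below
#' the ligand ceiling unless their code is on the keep-list; retains (and
#' flags) oversized het entities; completes missing side-chain atoms from
#' ideal residue templates; places polar hydrogens geometrically. Removed
#' ligands are recorded for later pocket-overlap analysis.
#'
#' @param s a `flexsite_structure` from [read_structure()]
#' @param keep_list cofactor codes to retain, default [default_keep_list()]
#' @param ligand_mw_max ligand definition ceiling in Da
#' @param add_hydrogens place polar hydrogens
#' @return a `prepared_structure` (subclass of `flexsite_structure`) with
#'   `retained_cofactors`, `removed_ligands`, `n_residues_per_chain`
#' @export
prepare <- function(s, keep_list = default_keep_list(), ligand_mw_max = 1000,
                    add_hydrogens = TRUE) {
  atoms <- s$atoms
  if (!any(!atoms$is_het)) stop("no protein atoms in structure")
  atoms <- atoms[!(toupper(atoms$resid) %in% .water_codes), , drop = FALSE]

  het <- atoms[atoms$is_het, , drop = FALSE]
  removed <- data.frame(resid = character(), chain = character(),
                        resno = integer(), mw = numeric(),
                        stringsAsFactors = FALSE)
  removed_atoms <- list()
  retained <- character()
  oversized <- character()
  if (nrow(het) > 0) {
    for (k in unique(het_entity_key(het))) {
      e <- het[het_entity_key(het) == k, , drop = FALSE]
      code <- toupper(e$resid[1])
      mw <- het_entity_mw(e)
      if (code %in% toupper(keep_list)) {
        retained <- c(retained, code)
      } else if (mw > ligand_mw_max) {
        retained <- c(retained, code)
        oversized <- c(oversized, code)
      } else {
        removed <- rbind(removed, data.frame(
          resid = code, chain = e$chain[1], resno = e$resno[1], mw = mw,
          stringsAsFactors = FALSE))
        removed_atoms[[k]] <- e
        atoms <- atoms[!(atoms$is_het & het_entity_key(atoms) == k), , drop = FALSE]
      }
    }
  }

  atoms <- complete_side_chains(atoms)
  if (add_hydrogens) atoms <- place_polar_hydrogens(atoms)

  prot <- atoms[!atoms$is_het, , drop = FALSE]
  nres <- vapply(split(paste(prot$resno, prot$insert), prot$chain),
                 function(v) length(unique(v)), integer(1))
  structure(list(
    atoms = atoms, source = s$source,
    retained_cofactors = unique(retained),
    oversized_het = unique(oversized),
    removed_ligands = removed,
    removed_ligand_atoms = if (length(removed_atoms))
      do.call(rbind, removed_atoms) else NULL,
    n_residues_per_chain = nres
  ), class = c("prepared_structure", "flexsite_structure"))
}

# --- residue templates (CCD ideal geometry) --------------------------------

aa_templates <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "aa_templates.tsv", package = "flexsite")
      cache <<- utils::read.delim(path, stringsAsFactors = FALSE)
    }
    cache
  }
})

.backbone_names <- c("N", "CA", "C", "O", "OXT")

complete_side_chains <- function(atoms) {
  tmpl <- aa_templates()
  prot <- which(!atoms$is_het)
  key <- paste(atoms$chain, atoms$resno, atoms$insert)
  new_rows <- list()
  for (k in unique(key[prot])) {
    idx <- which(key == k & !atoms$is_het)
    res <- toupper(atoms$resid[idx[1]])
    tt <- tmpl[tmpl$resname == res & tmpl$element != "H", , drop = FALSE]
    if (nrow(tt) == 0) next
    have <- toupper(atoms$elety[idx])
    missing <- setdiff(tt$atom, c(have, "OXT"))
    if (!length(missing)) next
    shared <- intersect(c("N", "CA", "C", "CB", "O"), intersect(tt$atom, have))
    if (length(shared) < 3) next
    fit <- superpose_fit(as.matrix(tt[match(shared, tt$atom), c("x", "y", "z")]),
                         as.matrix(atoms[idx[match(shared, have)], c("x", "y", "z")]))
    mxyz <- fit(as.matrix(tt[match(missing, tt$atom), c("x", "y", "z")]))
    proto <- atoms[idx[1], , drop = FALSE]
    for (i in seq_along(missing)) {
      r <- proto
      r$elety <- missing[i]
      r$element <- substr(gsub("[0-9]", "", missing[i]), 1, 1)
      r$x <- mxyz[i, 1]; r$y <- mxyz[i, 2]; r$z <- mxyz[i, 3]
      new_rows[[length(new_rows) + 1]] <- r
    }
  }
  if (length(new_rows)) atoms <- rbind(atoms, do.call(rbind, new_rows))
  atoms[order(atoms$chain, atoms$resno, atoms$insert, atoms$is_het), , drop = FALSE]
}

# Polar hydrogens: backbone amide H by the bisector rule; side-chain polar H
# mapped from the residue template through a local three-atom frame. Default
# protonation states: Asp/Glu deprotonated, Lys/Arg protonated, His neutral
# N-epsilon tautomer (the template hydrogens realize these states; Asp/Glu
# acid hydrogens and the His N-delta proton are skipped).
.skip_hydrogens <- list(ASP = "HD2", GLU = "HE2", HIS = "HD1")

place_polar_hydrogens <- function(atoms) {
  tmpl <- aa_templates()
  key <- paste(atoms$chain, atoms$resno, atoms$insert)
  prot_keys <- unique(key[!atoms$is_het])
  new_rows <- list()
  for (ki in seq_along(prot_keys)) {
    k <- prot_keys[ki]
    idx <- which(key == k & !atoms$is_het)
    res <- toupper(atoms$resid[idx[1]])
    tt <- tmpl[tmpl$resname == res, , drop = FALSE]
    if (nrow(tt) == 0) next
    have <- toupper(atoms$elety[idx])
    th <- tt[tt$element == "H", , drop = FALSE]
    txyz <- as.matrix(tt[, c("x", "y", "z")])
    theavy <- tt[tt$element != "H", , drop = FALSE]
    for (j in seq_len(nrow(th))) {
      hname <- th$atom[j]
      if (hname %in% have) next
      if (hname %in% .skip_hydrogens[[res]]) next
      hxyz <- as.numeric(th[j, c("x", "y", "z")])
      d <- sqrt(colSums((t(as.matrix(theavy[, c("x", "y", "z")])) - hxyz)^2))
      parent <- theavy$atom[which.min(d)]
      pel <- theavy$element[which.min(d)]
      if (!pel %in% c("N", "O", "S")) next       # polar hydrogens only
      if (!parent %in% have) next
      if (parent == "N") {                        # backbone amide: bisector rule
        r <- amide_hydrogen(atoms, idx, have)
        if (!is.null(r)) new_rows[[length(new_rows) + 1]] <- r
        next
      }
      # local frame: parent + its two nearest heavies present in the residue
      pd <- sqrt(colSums((t(as.matrix(theavy[, c("x", "y", "z")])) -
                          as.numeric(theavy[match(parent, theavy$atom), c("x", "y", "z")]))^2))
      frame <- theavy$atom[order(pd)][1:min(3, nrow(theavy))]
      frame <- frame[frame %in% have]
      if (length(frame) < 3) next
      fit <- superpose_fit(as.matrix(theavy[match(frame, theavy$atom), c("x", "y", "z")]),
                           as.matrix(atoms[idx[match(frame, have)], c("x", "y", "z")]))
      hx <- fit(matrix(hxyz, 1, 3))
      r <- atoms[idx[1], , drop = FALSE]
      r$elety <- hname; r$element <- "H"
      r$x <- hx[1]; r$y <- hx[2]; r$z <- hx[3]
      new_rows[[length(new_rows) + 1]] <- r
    }
  }
  if (length(new_rows)) atoms <- rbind(atoms, do.call(rbind, new_rows))
  atoms
}

amide_hydrogen <- function(atoms, idx, have) {
  if ("H" %in% have || !all(c("N", "CA") %in% have)) return(NULL)
  n <- as.numeric(atoms[idx[match("N", have)], c("x", "y", "z")])
  ca <- as.numeric(atoms[idx[match("CA", have)], c("x", "y", "z")])
  # previous residue carbonyl carbon: nearest C atom named "C" within 1.6 A
  allc <- atoms[!atoms$is_het & toupper(atoms$elety) == "C", , drop = FALSE]
  d <- sqrt((allc$x - n[1])^2 + (allc$y - n[2])^2 + (allc$z - n[3])^2)
  prev <- which(d > 0.1 & d < 1.6)
  if (!length(prev)) return(NULL)
  cp <- as.numeric(allc[prev[1], c("x", "y", "z")])
  u1 <- (n - ca) / sqrt(sum((n - ca)^2))
  u2 <- (n - cp) / sqrt(sum((n - cp)^2))
  dir <- u1 + u2
  dir <- dir / sqrt(sum(dir^2))
  h <- n + 1.01 * dir
  r <- atoms[idx[1], , drop = FALSE]
  r$elety <- "H"; r$element <- "H"
  r$x <- h[1]; r$y <- h[2]; r$z <- h[3]
  r
}

# --- coordinate access and writing -----------------------------------------

#' Heavy-atom coordinates of a structure
#' @param s `flexsite_structure`
#' @param het include het atoms
#' @return n x 3 matrix
#' @export
heavy_xyz <- function(s, het = TRUE) {
  a <- s$atoms
  sel <- a$element != "H" & (het | !a$is_het)
  as.matrix(a[sel, c("x", "y", "z")])
}

heavy_atoms <- function(s, het = TRUE) {
  a <- s$atoms
  a[a$element != "H" & (het | !a$is_het), , drop = FALSE]
}

#' Write a structure as a PDB file
#' @param s `flexsite_structure`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_structure <- function(s, path) {
  a <- s$atoms
  bio3d::write.pdb(file = path, type = a$type, eleno = seq_len(nrow(a)),
                   elety = a$elety, resid = a$resid, chain = a$chain,
                   resno = a$resno, xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   o = a$o, b = a$b, elesy = a$element)
  invisible(path)
}

#' Write site points as HETATM pseudo-atoms for visualization
#' @param points n x 3 coordinate matrix
#' @param path output PDB file
#' @return `path`, invisibly
#' @export
write_site_points <- function(points, path) {
  n <- nrow(points)
  bio3d::write.pdb(file = path, type = rep("HETATM", n), eleno = seq_len(n),
                   elety = rep("DU", n), resid = rep("STP", n),
                   chain = rep("X", n), resno = rep(1L, n),
                   xyz = as.numeric(t(points)), o = rep(0, n), b = rep(0, n),
                   elesy = rep("X", n))
  invisible(path)
}

#' Write the ligand-removal log as JSON
#' @param s `prepared_structure`
#' @param path output JSON file
#' @return `path`, invisibly
#' @export
write_removal_log <- function(s, path) {
  jsonlite::write_json(list(
    retained_cofactors = s$retained_cofactors,
    oversized_het = s$oversized_het,
    removed_ligands = s$removed_ligands
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.flexsite_structure <- function(x, ...) {
  a <- x$atoms
  cat("flexsite structure:", nrow(a), "atoms,",
      length(unique(a$chain[!a$is_het])), "protein chain(s)\n")
  if (inherits(x, "prepared_structure")) {
    cat("  prepared; removed ligands:", nrow(x$removed_ligands),
        "; retained cofactors:", paste(x$retained_cofactors, collapse = " "), "\n")
  }
  invisible(x)
}
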