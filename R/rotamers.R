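# Side-chain chi-angle machinery and a compact backbone-independent rotamer
# set: canonical gauche-/trans/gauche+ targets per chi with +/-30 degree
# sub-sampling around the best base rotamer.

.chi_defs <- list(
  SER = list(c("N", "CA", "CB", "OG")),
  CYS = list(c("N", "CA", "CB", "SG")),
  THR = list(c("N", "CA", "CB", "OG1")),
  VAL = list(c("N", "CA", "CB", "CG1")),
  LEU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  ILE = list(c("N", "CA", "CB", "CG1"), c("CA", "CB", "CG1", "CD1")),
  ASP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  ASN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  HIS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "ND1")),
  PHE = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  TYR = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  TRP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  MET = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "SD"),
             c("CB", "CG", "SD", "CE")),
  GLU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  GLN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  LYS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "CE"), c("CG", "CD", "CE", "NZ")),
  ARG = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "NE"), c("CG", "CD", "NE", "CZ"))
)

.chi_base <- c(-60, 180, 60) * pi / 180

#' Residue types with rotamer support
#' @return character vector of 3-letter codes
#' @export
rotatable_residues <- function() names(.chi_defs)

# current chi angles (radians) of a residue given its atoms data frame
residue_chi_values <- function(res) {
  defs <- .chi_defs[[toupper(res$resid[1])]]
  if (is.null(defs)) return(numeric())
  nm <- toupper(res$elety)
  vapply(defs, function(d) {
    idx <- match(d, nm)
    if (anyNA(idx)) return(NA_real_)
    dihedral(as.numeric(res[idx[1], c("x", "y", "z")]),
             as.numeric(res[idx[2], c("x", "y", "z")]),
             as.numeric(res[idx[3], c("x", "y", "z")]),
             as.numeric(res[idx[4], c("x", "y", "z")]))
  }, numeric(1))
}

# Atoms displaced when chi k rotates: everything on the far side of the
# b-c bond, found from distance-based covalent adjacency within the residue.
residue_adjacency <- function(res) {
  xyz <- as.matrix(res[, c("x", "y", "z")])
  n <- nrow(xyz)
  d <- as.matrix(stats::dist(xyz))
  lim <- outer(ifelse(res$element %in% c("S", "P"), 2.2, 1.9) / 2,
               ifelse(res$element %in% c("S", "P"), 2.2, 1.9) / 2, "+")
  d > 0.1 & d < lim
}

chi_moved_atoms <- function(res, chi_def) {
  nm <- toupper(res$elety)
  b <- match(chi_def[3], nm)
  a <- match(chi_def[2], nm)
  if (is.na(a) || is.na(b)) return(integer())
  adj <- residue_adjacency(res)
  seen <- rep(FALSE, nrow(res)); seen[b] <- TRUE
  queue <- b
  while (length(queue)) {
    i <- queue[[1]]; queue <- queue[-1]
    for (j in which(adj[i, ])) {
      if (j == a && i == b) next
      if (!seen[j]) { seen[j] <- TRUE; queue <- c(queue, j) }
    }
  }
  seen[b] <- FALSE
  which(seen)
}

#' Set the chi angles of a residue
#'
#' Rotates side-chain atoms about each chi axis so the dihedrals take the
#' target values (radians). Backbone and CB stay fixed.
#'
#' @param res residue atoms data frame (x, y, z, elety, resid, element)
#' @param targets numeric vector of chi targets, NA to leave a chi unchanged
#' @return the residue with updated coordinates
#' @export
set_residue_chis <- function(res, targets) {
  defs <- .chi_defs[[toupper(res$resid[1])]]
  if (is.null(defs)) return(res)
  nm <- toupper(res$elety)
  for (k in seq_along(targets)) {
    if (k > length(defs) || is.na(targets[k])) next
    cur <- residue_chi_values(res)[k]
    if (is.na(cur)) next
    idx <- match(defs[[k]], nm)
    moved <- chi_moved_atoms(res, defs[[k]])
    if (!length(moved)) next
    xyz <- as.matrix(res[, c("x", "y", "z")])
    xyz <- rotate_torsion(xyz, as.numeric(xyz[idx[2], ]), as.numeric(xyz[idx[3], ]),
                          cur - targets[k], moved)
    res$x <- xyz[, 1]; res$y <- xyz[, 2]; res$z <- xyz[, 3]
  }
  res
}

#' Enumerate candidate rotamers for a residue
#'
#' Base rotamers are the product of canonical chi targets (-60, 180, 60
#' degrees; chis beyond the second are held at their most common trans/gauche
#' targets to keep the set compact), ordered by a conventional frequency
#' preference, capped at `max_rotamers`. Each carries a small preference
#' penalty used by the repacking energy.
#'
#' @param res residue atoms data frame
#' @param max_rotamers cap on the number of candidates
#' @return list of `list(chis = <radians>, penalty = <number>)`
#' @export
residue_rotamers <- function(res, max_rotamers = 30) {
  defs <- .chi_defs[[toupper(res$resid[1])]]
  if (is.null(defs)) return(list())
  nchi <- length(defs)
  grids <- rep(list(.chi_base), min(nchi, 2))
  if (nchi > 2) grids <- c(grids, rep(list(c(180, -60, 60) * pi / 180), nchi - 2))
  combos <- expand.grid(grids)
  rot <- lapply(seq_len(nrow(combos)), function(i) {
    list(chis = as.numeric(combos[i, ]), penalty = 0.2 * (i - 1) / nrow(combos))
  })
  rot[seq_len(min(max_rotamers, length(rot)))]
}

# +/-30 degree sub-sampling around a chi vector
rotamer_subsample <- function(chis) {
  out <- list()
  for (k in seq_along(chis)) {
    for (dlt in c(-30, 30) * pi / 180) {
      v <- chis; v[k] <- v[k] + dlt
      out[[length(out) + 1]] <- list(chis = v, penalty = 0.1)
    }
  }
  out
}
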