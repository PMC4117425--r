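# Hydrophobic probe molecules used by the induced-fit procedure: rigid
# naphthalene for stage one, a tetra-substituted naphthalene (TSN, ~363 Da,
# ethyl / propyl / two cyclohexyl substituents) for stage two. Probes ship
# as SDF files; rotatable substituent bonds are detected as bridge bonds of
# the heavy-atom graph.

#' Load a packaged probe molecule
#'
#' @param name `"naphthalene"`, `"tsn"`, or a path to an SDF file
#' @return a `probe`: element vector, coordinates, hydrogen flags,
#'   molecular weight (Da, hydrogens included) and rotatable-bond list
#' @export
load_probe <- function(name) {
  path <- if (file.exists(name)) name else
    system.file("extdata", paste0(tolower(name), ".sdf"), package = "flexsite")
  if (!nzchar(path) || !file.exists(path)) stop("unknown probe: ", name)
  sdf <- ChemmineR::read.SDFset(path)[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  element <- toupper(gsub("_.*$", "", rownames(ab)))
  xyz <- unname(as.matrix(ab[, 1:3]))
  is_h <- element == "H"
  bonds <- cbind(as.integer(bb[, 1]), as.integer(bb[, 2]))
  structure(list(
    name = tools::file_path_sans_ext(basename(path)),
    element = element, xyz = xyz, is_h = is_h, bonds = bonds,
    molecular_weight = sum(element_mass(element)),
    rotatable = rotatable_bonds(element, bonds, is_h)
  ), class = "probe")
}

# bridge bonds between heavy atoms whose smaller side carries >= 2 heavy
# atoms; `moved` holds the atom indices (including hydrogens) on the smaller
# side, which the torsion rotation displaces
rotatable_bonds <- function(element, bonds, is_h) {
  n <- length(element)
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  reach <- function(from, blocked_a, blocked_b) {
    seen <- rep(FALSE, n); seen[from] <- TRUE
    queue <- from
    while (length(queue)) {
      i <- queue[[1]]; queue <- queue[-1]
      for (j in adj[[i]]) {
        if ((i == blocked_a && j == blocked_b) || (i == blocked_b && j == blocked_a)) next
        if (!seen[j]) { seen[j] <- TRUE; queue <- c(queue, j) }
      }
    }
    seen
  }
  out <- list()
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    if (is_h[i] || is_h[j]) next
    side <- reach(j, i, j)
    if (side[i]) next                       # in a cycle, not a bridge
    heavy_side <- sum(side & !is_h)
    if (heavy_side >= 2 && heavy_side <= n - heavy_side) {
      out[[length(out) + 1]] <- list(a = i, b = j, moved = which(side))
    } else if ((n - heavy_side) >= 2 && (n - heavy_side) < heavy_side) {
      out[[length(out) + 1]] <- list(a = j, b = i, moved = which(!side))
    }
  }
  out
}

#' Generate probe conformers by substituent torsion sampling
#'
#' Rotates each rotatable bond on a fixed angular grid (`torsion_step`
#' degrees), enumerates combinations in a deterministic order, drops
#' self-clashing geometries and keeps at most `max_conformers` by internal
#' energy. A rigid probe returns its input geometry.
#'
#' @param probe a `probe`
#' @param cfg [flex_config()]
#' @return list of coordinate matrices (all atoms)
#' @export
probe_conformers <- function(probe, cfg = flex_config()) {
  rb <- probe$rotatable
  if (!length(rb)) return(list(probe$xyz))
  angles <- seq(0, 359, by = cfg$torsion_step) * pi / 180
  nb <- length(rb)
  combos <- expand.grid(rep(list(seq_along(angles)), nb))
  # deterministic thinning to a workable enumeration
  if (nrow(combos) > 240) combos <- combos[seq(1, nrow(combos), length.out = 240), , drop = FALSE]
  out <- list()
  scores <- numeric()
  for (r in seq_len(nrow(combos))) {
    xyz <- probe$xyz
    for (bi in seq_len(nb)) {
      ang <- angles[combos[r, bi]]
      if (ang == 0) next
      xyz <- rotate_torsion(xyz, xyz[rb[[bi]]$a, ], xyz[rb[[bi]]$b, ], ang, rb[[bi]]$moved)
    }
    en <- internal_clash_energy(xyz, probe)
    if (en < 1e3) { out[[length(out) + 1]] <- xyz; scores <- c(scores, en) }
  }
  if (!length(out)) return(list(probe$xyz))
  out[order(scores)][seq_len(min(cfg$max_conformers, length(out)))]
}

# soft internal energy: repulsion between non-bonded heavy-atom pairs
internal_clash_energy <- function(xyz, probe) {
  hv <- which(!probe$is_h)
  d <- as.matrix(stats::dist(xyz[hv, , drop = FALSE]))
  bonded <- matrix(FALSE, length(hv), length(hv))
  idx <- match(seq_along(probe$element), hv)
  for (k in seq_len(nrow(probe$bonds))) {
    i <- idx[probe$bonds[k, 1]]; j <- idx[probe$bonds[k, 2]]
    if (!is.na(i) && !is.na(j)) bonded[i, j] <- bonded[j, i] <- TRUE
  }
  # also exclude 1-3 pairs
  b13 <- bonded %*% bonded > 0
  mask <- !bonded & !b13 & upper.tri(d)
  sum(pmax(0, 2.8 - d[mask])^2 * 10)
}

#' @export
print.probe <- function(x, ...) {
  cat("probe", x$name, ":", sum(!x$is_h), "heavy atoms, MW",
      round(x$molecular_weight, 1), "Da,", length(x$rotatable),
      "rotatable bond(s)\n")
  invisible(x)
}
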