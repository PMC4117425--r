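# Element parameter tables: van der Waals radii (A), Lennard-Jones half-rmin
# (A) and well depths (kcal/mol) for a united-atom treatment, and standard
# atomic masses (Da). Values are conventional united-atom constants; the
# probe half-rmin is chosen so the probe-carbon pair minimum sits at 4.0 A.

.element_table <- data.frame(
  element = c("H", "C", "N", "O", "S", "P", "F", "CL", "BR", "I",
              "SE", "ZN", "MG", "FE", "MN", "CU", "NA", "K", "CA", "NI", "CO"),
  vdw     = c(1.09, 1.70, 1.55, 1.52, 1.80, 1.80, 1.47, 1.75, 1.85, 1.98,
              1.90, 1.39, 1.73, 1.52, 1.61, 1.40, 2.27, 2.75, 2.31, 1.63, 1.53),
  rmin2   = c(1.20, 2.00, 1.90, 1.85, 2.10, 2.10, 1.70, 2.00, 2.15, 2.30,
              2.20, 1.60, 1.90, 1.70, 1.80, 1.60, 2.40, 2.90, 2.45, 1.80, 1.70),
  eps     = c(0.02, 0.15, 0.17, 0.21, 0.25, 0.20, 0.06, 0.27, 0.32, 0.40,
              0.29, 0.25, 0.88, 0.01, 0.01, 0.01, 0.05, 0.10, 0.12, 0.01, 0.01),
  mass    = c(1.008, 12.011, 14.007, 15.999, 32.06, 30.974, 18.998, 35.45,
              79.904, 126.904, 78.971, 65.38, 24.305, 55.845, 54.938, 63.546,
              22.990, 39.098, 40.078, 58.693, 58.933),
  stringsAsFactors = FALSE
)

# single united-atom sp3-carbon-like probe; pair rmin with carbon = 4.0 A
.probe_params <- list(rmin2 = 2.0, eps = 0.15)

.elem_lookup <- function(elements, column, default) {
  idx <- match(toupper(elements), .element_table$element)
  out <- .element_table[[column]][idx]
  out[is.na(out)] <- default
  out
}

#' Van der Waals radii for element symbols
#' @param elements character vector of element symbols
#' @return numeric vector of radii in Angstrom (1.70 for unknown elements)
#' @export
element_vdw <- function(elements) .elem_lookup(elements, "vdw", 1.70)

#' Standard atomic masses for element symbols
#' @param elements character vector of element symbols
#' @return numeric vector of masses in Da (12.011 for unknown elements)
#' @export
element_mass <- function(elements) .elem_lookup(elements, "mass", 12.011)

element_rmin2 <- function(elements) .elem_lookup(elements, "rmin2", 2.0)
element_eps <- function(elements) .elem_lookup(elements, "eps", 0.15)

# Pair LJ parameters of the site probe against receptor atoms
# (Lorentz-Berthelot combination).
probe_pair_params <- function(elements) {
  list(
    rmin = .probe_params$rmin2 + element_rmin2(elements),
    eps = sqrt(.probe_params$eps * element_eps(elements))
  )
}

# Atom-level polarity classification used by the phobic/philic fields.
# Polar: N and O everywhere, S outside Cys/Met thioether/thiol context.
# Apolar: carbons plus Cys/Met sulfurs. Charged side-chain atoms get double
# weight in the hydrophilic kernel.
.charged_atoms <- c(
  "ASP OD1", "ASP OD2", "GLU OE1", "GLU OE2",
  "LYS NZ", "ARG NE", "ARG NH1", "ARG NH2"
)

atom_polarity <- function(elements, resnames, atomnames) {
  el <- toupper(elements)
  res <- toupper(resnames)
  polar <- el %in% c("N", "O") | (el == "S" & !(res %in% c("CYS", "MET")))
  apolar <- el == "C" | (el == "S" & res %in% c("CYS", "MET"))
  charged <- paste(res, toupper(atomnames)) %in% .charged_atoms
  list(polar = polar, apolar = apolar,
       weight = ifelse(charged, 2, 1))
}
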