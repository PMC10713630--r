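## Reference tables: atomic masses, van der Waals radii, hydrophobicity
## scales, residue similarity groups. All keyed by upper-case symbols.

# Standard atomic masses (u) for elements common in biomolecular files.
.atomic_masses <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, F = 18.998, CL = 35.45, BR = 79.904, I = 126.904,
  "NA" = 22.990, K = 39.098, MG = 24.305, CA = 40.078, ZN = 65.38,
  FE = 55.845, MN = 54.938, CU = 63.546, SE = 78.971, B = 10.81
)

# Bondi-style van der Waals radii (Angstrom); fallback for elements not
# listed is 1.7 (carbon-like), used by the PQR defaulting path too.
.vdw_radii <- c(
  H = 1.20, D = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
  P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
  "NA" = 2.27, K = 2.75, MG = 1.73, CA = 2.31, ZN = 1.39,
  FE = 1.52, MN = 1.61, CU = 1.40, SE = 1.90, B = 1.92
)
.default_vdw <- 1.7

#' Van der Waals radius lookup by element
#'
#' @param element character vector of element symbols.
#' @return numeric vector of radii in Angstrom; unknown elements get the
#'   carbon-like fallback of 1.7 Angstrom.
#' @export
vdw_radius <- function(element) {
  r <- .vdw_radii[toupper(element)]
  r[is.na(r)] <- .default_vdw
  unname(r)
}

#' Atomic mass lookup by element
#'
#' @param element character vector of element symbols.
#' @return numeric vector of masses (u); unknown elements get the carbon
#'   mass so geometric results stay finite.
#' @export
atomic_mass <- function(element) {
  m <- .atomic_masses[toupper(element)]
  m[is.na(m)] <- .atomic_masses[["C"]]
  unname(m)
}

# Kyte-Doolittle hydropathy, sign-flipped so that HIGHER = MORE POLAR
# (hydrophilic). This is the bundled default for pocket polarity scoring.
.kd_polarity <- c(
  ALA = -1.8, ARG =  4.5, ASN =  3.5, ASP =  3.5, CYS = -2.5,
  GLN =  3.5, GLU =  3.5, GLY =  0.4, HIS =  3.2, ILE = -4.5,
  LEU = -3.8, LYS =  3.9, MET = -1.9, PHE = -2.8, PRO =  1.6,
  SER =  0.8, THR =  0.7, TRP =  0.9, TYR =  1.3, VAL = -4.2
)

# Wimley-White interface scale: free energy of transfer from water to a
# POPC interface (kcal/mol), charged Asp/Glu/Lys/Arg/His as charged.
# Positive = prefers water = more polar, so the orientation already
# matches the default scale: higher = more hydrophilic.
.ww_polarity <- c(
  ALA = 0.17, ARG = 0.81, ASN = 0.42, ASP = 1.23, CYS = -0.24,
  GLN = 0.58, GLU = 2.02, GLY = 0.01, HIS = 0.17, ILE = -0.31,
  LEU = -0.56, LYS = 0.99, MET = -0.23, PHE = -1.13, PRO = 0.45,
  SER = 0.13, THR = 0.14, TRP = -1.85, TYR = -0.94, VAL = 0.07
)

#' Bundled hydrophobicity scales
#'
#' Returns a named residue -> value vector oriented so that higher values
#' mean a more polar (hydrophilic) residue, whichever underlying scale is
#' chosen. `"kd"` is the Kyte-Doolittle hydropathy index, sign-flipped;
#' `"ww"` is the Wimley-White water-to-POPC-interface transfer scale,
#' whose native orientation (positive = prefers water) already points
#' this way.
#'
#' @param name `"kd"` (default) or `"ww"`.
#' @return object of class `HydrophobicityScale`: a named numeric vector
#'   over the 20 standard residues with a `name` attribute.
#' @export
hydrophobicity_scale <- function(name = c("kd", "ww")) {
  name <- match.arg(name)
  values <- switch(name, kd = .kd_polarity, ww = .ww_polarity)
  structure(values, name = name, class = "HydrophobicityScale")
}

# Atomic hydrophobicity constants by element for the MHP field.
# Carbon-rich regions are hydrophobic (positive); N/O hydrophilic.
.atomic_hydrophobicity <- c(
  C = 0.60, S = 0.40, F = 0.45, CL = 0.50, BR = 0.50, I = 0.50,
  H = 0.10, P = -0.30, N = -0.55, O = -0.70
)

#' Atomic hydrophobicity constants
#'
#' Per-element fragmental constants used by [mhp_field()]. Atoms carrying
#' an explicit `hydrophobicity` column in the structure override the
#' table. Unknown elements raise an error in [mhp_field()].
#'
#' @return named numeric vector, element -> constant.
#' @export
atomic_hydrophobicity_table <- function() .atomic_hydrophobicity

#' Default residue similarity groups
#'
#' Grouping used for "similar" residue pairs in conservation statistics:
#' aliphatic+Cys \{A,V,L,I,M,C\}, aromatic \{F,W,Y\}, hydroxyl \{S,T\},
#' basic \{K,R,H\}, acidic \{D,E\}, amide \{N,Q\}, and G, P alone.
#'
#' @return named list of character vectors of 1-letter codes.
#' @export
default_similarity_groups <- function() {
  list(
    aliphatic = c("A", "V", "L", "I", "M", "C"),
    aromatic  = c("F", "W", "Y"),
    hydroxyl  = c("S", "T"),
    basic     = c("K", "R", "H"),
    acidic    = c("D", "E"),
    amide     = c("N", "Q"),
    glycine   = "G",
    proline   = "P"
  )
}

# residue 3-letter <-> 1-letter maps
.aa3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
          "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL")
.aa1 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

#' Convert between 1- and 3-letter residue codes
#' @param x character vector of residue codes.
#' @return converted codes; unknown inputs become `NA`.
#' @export
aa_three_to_one <- function(x) {
  .aa1[match(toupper(x), .aa3)]
}

#' @rdname aa_three_to_one
#' @export
aa_one_to_three <- function(x) {
  .aa3[match(toupper(x), .aa1)]
}

# residue names recognised as water (configurable via options)
.water_resnames_default <- c("HOH", "WAT", "TIP3")

#' Residue names treated as water
#'
#' @param set optional character vector to install as the water residue
#'   name set for this session (via `options(cavitrack.water_resnames=)`).
#' @return the active character vector of water residue names.
#' @export
water_resnames <- function(set = NULL) {
  if (!is.null(set)) options(cavitrack.water_resnames = toupper(set))
  getOption("cavitrack.water_resnames", .water_resnames_default)
}
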