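# Physical constants and lookup tables shared across modules.

# Boltzmann constant in kJ/(mol K); energies throughout are molar.
KB_KJ_MOL_K <- 0.008314462618

# Angstrom -> nanometre conversion for reported distances.
ANG_TO_NM <- 0.1

# van der Waals radii (Angstrom), Bondi (1964) values for the elements
# that occur in protein/ligand heavy-atom models plus hydrogen.
VDW_RADII <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52,
  S = 1.80, P = 1.80, F = 1.47, CL = 1.75,
  BR = 1.85, I = 1.98
)

# Atomic masses (u) for mass-weighted geometry.
ATOMIC_MASSES <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999,
  S = 32.06, P = 30.974, F = 18.998, CL = 35.45,
  BR = 79.904, I = 126.904
)

# Eisenberg-Weiss consensus hydropathy scale (normalised consensus values,
# Eisenberg, Weiss & Terwilliger 1984).  Positive = hydrophobic.
EISENBERG_WEISS <- c(
  ALA =  0.62, ARG = -2.53, ASN = -0.78, ASP = -0.90, CYS = 0.29,
  GLN = -0.85, GLU = -0.74, GLY =  0.48, HIS = -0.40, ILE = 1.38,
  LEU =  1.06, LYS = -1.50, MET =  0.64, PHE =  1.19, PRO = 0.12,
  SER = -0.18, THR = -0.05, TRP =  0.81, TYR =  0.26, VAL = 1.08
)

#' Mean Eisenberg-Weiss hydropathy of a residue set
#'
#' Arithmetic mean of the consensus-scale hydropathy values of the given
#' residues.  Cavities with mean hydropathy at or below zero are treated
#' as hydrophobic-leaning during binding-site selection.
#'
#' @param residue_names character vector of three-letter amino-acid codes
#'   (case-insensitive).
#' @return mean hydropathy (scale units).
#' @export
#' @examples
#' eisenberg_weiss_hydropathy(c("LEU", "LYS"))
eisenberg_weiss_hydropathy <- function(residue_names) {
  if (length(residue_names) == 0L) {
    stop("residue_names must be non-empty")
  }
  key <- toupper(residue_names)
  unknown <- setdiff(unique(key), names(EISENBERG_WEISS))
  if (length(unknown) > 0L) {
    stop("unknown residue name(s): ", paste(unknown, collapse = ", "))
  }
  mean(EISENBERG_WEISS[key])
}

vdw_radius <- function(element) {
  key <- toupper(element)
  r <- VDW_RADII[key]
  if (anyNA(r)) {
    stop("no van der Waals radius for element(s): ",
         paste(unique(element[is.na(r)]), collapse = ", "))
  }
  unname(r)
}

atomic_mass <- function(element) {
  key <- toupper(element)
  m <- ATOMIC_MASSES[key]
  if (anyNA(m)) {
    stop("no atomic mass for element(s): ",
         paste(unique(element[is.na(m)]), collapse = ", "))
  }
  unname(m)
}
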