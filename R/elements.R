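# Element data used across the package. Radii in Angstrom.

# Covalent radii (Cordero et al. single-bond values, rounded) for bond
# inference: a pair is bonded when d < 1.3 * (r_i + r_j).
.covalent_radii <- c(
  H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57, P = 1.07, S = 1.05,
  CL = 1.02, BR = 1.20, I = 1.39, "NA" = 1.66, K = 2.03, MG = 1.41,
  CA = 1.76, ZN = 1.22, FE = 1.32
)

# Bondi van der Waals radii for grid-based molecular volume.
.vdw_radii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80, S = 1.80,
  CL = 1.75, BR = 1.85, I = 1.98
)

.known_elements <- union(names(.covalent_radii), names(.vdw_radii))

#' Van der Waals radius lookup
#'
#' @param element character vector of element symbols.
#' @return numeric vector of Bondi radii in Angstrom.
#' @keywords internal
vdw_radius <- function(element) {
  key <- toupper(element)
  bad <- setdiff(unique(key), names(.vdw_radii))
  if (length(bad) > 0) {
    abort(paste0("no van der Waals radius for element(s): ",
                 paste(bad, collapse = ", ")))
  }
  unname(.vdw_radii[key])
}

covalent_radius <- function(element) {
  key <- toupper(element)
  r <- .covalent_radii[key]
  r[is.na(r)] <- 0.77 # fallback: carbon-like
  unname(r)
}

# ---- residue templates -----------------------------------------------------
# Donor/acceptor/apolar/ring/charge templates for the 20 standard residues,
# used when a protein arrives without explicit hydrogens or bonds (the usual
# case for PDB input). Ligand atoms are typed from their bond graph instead.

# backbone N is a donor, backbone O (and OXT) acceptors, for every residue
.template_donors <- list(
  SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG",
  ASN = "ND2", GLN = "NE2", HIS = c("ND1", "NE2"), TRP = "NE1",
  LYS = "NZ", ARG = c("NE", "NH1", "NH2")
)

.template_acceptors <- list(
  SER = "OG", THR = "OG1", TYR = "OH",
  ASN = "OD1", GLN = "OE1", HIS = c("ND1", "NE2"),
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), MET = "SD"
)

# side-chain carbons bonded only to C/H in the standard topology
.template_apolar <- list(
  ALA = "CB",
  VAL = c("CB", "CG1", "CG2"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  ILE = c("CB", "CG1", "CG2", "CD1"),
  PRO = c("CB", "CG"),
  MET = "CB",
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2"),
  TRP = c("CB", "CG", "CD1", "CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  LYS = c("CB", "CG", "CD"),
  ARG = c("CB", "CG"),
  GLU = c("CB", "CG"),
  GLN = c("CB", "CG"),
  ASP = "CB",
  ASN = "CB",
  HIS = "CB",
  THR = "CG2"
)

.template_rings <- list(
  PHE = list(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")),
  TYR = list(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")),
  HIS = list(c("CG", "ND1", "CE1", "NE2", "CD2")),
  TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
             c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3"))
)

# charged group template: atoms whose centroid carries the formal charge
.template_charges <- list(
  LYS = list(list(atoms = "NZ", sign = +1L)),
  ARG = list(list(atoms = c("NE", "NH1", "NH2"), sign = +1L)),
  ASP = list(list(atoms = c("OD1", "OD2"), sign = -1L)),
  GLU = list(list(atoms = c("OE1", "OE2"), sign = -1L))
)

.standard_residues <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)
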