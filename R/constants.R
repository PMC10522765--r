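# Package-wide unit conventions: coordinates in Angstrom, times in ps,
# energies in kcal/mol, masses in amu, charges in elementary charges,
# temperatures in K.

#' Physical constants used by nuctraj
#'
#' Electrostatic and thermodynamic constants in the package unit system
#' (Angstrom, kcal/mol, amu, elementary charge, Kelvin).
#'
#' @format A named list with elements:
#' \describe{
#'   \item{ke}{Coulomb constant, 332.0637 kcal mol^-1 A e^-2 (Amber convention).}
#'   \item{kB}{Boltzmann constant, kcal mol^-1 K^-1.}
#'   \item{kB_J}{Boltzmann constant, J K^-1.}
#'   \item{hbar_J}{Reduced Planck constant, J s.}
#'   \item{amu_kg}{Atomic mass unit, kg.}
#' }
#' @export
nuctraj_constants <- list(
  ke      = 332.0637,          # kcal*A/(mol*e^2)
  kB      = 1.987204259e-3,    # kcal/(mol*K)
  kB_J    = 1.380649e-23,      # J/K
  hbar_J  = 1.054571817e-34,   # J*s
  amu_kg  = 1.66053906660e-27  # kg
)

# Dimensionless prefactor alpha(T) such that, for an eigenvalue lambda of the
# mass-weighted covariance in amu*A^2, the Schlitter argument is 1 + alpha*lambda.
# alpha = kB*T*e^2/hbar^2, expressed per (amu * A^2).
schlitter_alpha <- function(temperature) {
  with(nuctraj_constants,
       kB_J * temperature * exp(2) / hbar_J^2 * amu_kg * 1e-20)
}

# Atom role labels used across the package.
ATOM_ROLES <- c("base", "nucleic_backbone", "protein_sidechain",
                "protein_backbone", "other")

# Default element masses (amu) for classification and mass-weighting when a
# parameter table has not been loaded.
ELEMENT_MASSES <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.973762, S = 32.06,
  ZN = 65.38, NA. = 22.99, K = 39.098, MG = 24.305, CL = 35.45, F = 18.998
)

# Single-bond covalent radii (A) for distance-based bond inference.
COVALENT_RADII <- c(
  H = 0.31, C = 0.76, N = 0.71, O = 0.66, P = 1.07, S = 1.05,
  ZN = 1.22, NA. = 1.66, K = 2.03, MG = 1.41, CL = 1.02, F = 0.57
)

lookup_element_value <- function(table, element, default) {
  key <- ifelse(element == "NA", "NA.", element)
  out <- unname(table[key])
  out[is.na(out)] <- default
  out
}

# Residue-name tables for polymer-kind assignment.  Trailing 3/5 terminal tags
# (DA5, DT3, RU5, ...) are stripped before lookup.
PROTEIN_RESNAMES <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "HID", "HIE", "HIP", "CYX", "ASH", "GLH", "LYN"
)
NUCLEIC_RESNAMES <- c(
  "DA", "DC", "DG", "DT", "DU", "DI",
  "A", "C", "G", "U", "I",
  "RA", "RC", "RG", "RU",
  "ADE", "GUA", "CYT", "THY", "URA"
)
PURINE_RESNAMES    <- c("DA", "DG", "DI", "A", "G", "I", "RA", "RG", "ADE", "GUA")

normalize_resname <- function(resname) {
  out <- toupper(trimws(resname))
  sub("^(D?[ACGTUI]|R[ACGU])[35]$", "\\1", out)
}

# Protein backbone atom names: N, CA, C, O (+ their hydrogens) and terminal
# atoms.  HA counts as backbone for every residue, so glycine has an empty
# heavy-atom side chain.
PROTEIN_BACKBONE_ATOMS <- c(
  "N", "CA", "C", "O", "OXT", "H", "HN", "H1", "H2", "H3",
  "HA", "HA1", "HA2", "HA3"
)

# Nucleic backbone: phosphate plus the full sugar (including O2'/HO2' of RNA).
NUCLEIC_BACKBONE_ATOMS <- c(
  "P", "OP1", "OP2", "OP3", "O1P", "O2P", "O3P",
  "O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "O2'", "C1'",
  "H5'", "H5''", "H4'", "H3'", "H2'", "H2''", "H1'",
  "HO2'", "HO5'", "HO3'", "HO'2"
)

normalize_atom_name <- function(name) {
  gsub("\\*", "'", toupper(trimws(name)))
}

# Cationic protein nitrogens eligible for salt bridges (His only if the
# protonated flag is set).
CATIONIC_ATOMS <- list(
  ARG = c("NH1", "NH2", "NE"),
  LYS = c("NZ"),
  HIS_PROTONATED = c("ND1", "NE2")
)
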