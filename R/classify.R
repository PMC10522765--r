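#' Classify atoms into interaction roles
#'
#' Assigns every atom one of the roles `base`, `nucleic_backbone`,
#' `protein_sidechain`, `protein_backbone` or `other`.  The split encodes the
#' specific/nonspecific contact partition: sequence read-out happens between
#' protein side chains and nucleobases, while phosphate/sugar and protein
#' backbone atoms mediate nonspecific (shape and electrostatic) read-out.
#'
#' Conventions: the nucleic backbone is the phosphate plus the complete sugar
#' including O2'/HO2' of RNA; the base is the nucleobase ring system with its
#' exocyclic substituents and hydrogens.  Protein backbone is N, CA, C, O,
#' their hydrogens (HA included, so glycine has no heavy side-chain atoms) and
#' terminal OXT; everything else on a protein residue is side chain.
#'
#' @param system A [mol_system].
#' @return The system with the `role` column of the atom table set.
#' @export
classify_atoms <- function(system) {
  a <- system$atoms
  polymer <- system$residues$polymer[a$res_index]
  role <- rep("other", nrow(a))

  is_nuc <- polymer == "nucleic"
  role[is_nuc] <- ifelse(a$name[is_nuc] %in% NUCLEIC_BACKBONE_ATOMS,
                         "nucleic_backbone", "base")

  is_pro <- polymer == "protein"
  role[is_pro] <- ifelse(a$name[is_pro] %in% PROTEIN_BACKBONE_ATOMS,
                         "protein_backbone", "protein_sidechain")

  if (any(polymer == "other")) {
    warning("atoms in residues of unknown polymer kind kept as role 'other': ",
            paste(unique(a$resname[polymer == "other"]), collapse = ", "))
  }
  a$role <- role
  system$atoms <- a
  system
}

#' Role counts per residue
#'
#' Convenience summary used to audit the role partition.
#'
#' @param system A classified [mol_system].
#' @param heavy_only Count heavy atoms only (default `TRUE`).
#' @return Tibble with one row per (residue, role) and column `n`.
#' @export
role_counts <- function(system, heavy_only = TRUE) {
  a <- system$atoms
  if (all(is.na(a$role))) stop("roles not set; run classify_atoms() first")
  if (heavy_only) a <- a[a$is_heavy, ]
  dplyr::count(a, .data$res_index, .data$resname, .data$role, name = "n")
}
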