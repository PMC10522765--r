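# Standard nucleobase geometries in the standard base reference frame
# (x toward the major groove, y along the C1'-C1' sense toward the backbone
# of the reference strand, z the stacking normal; base atoms in the z = 0
# plane).  These planar geometries are the conventional standard-base
# embedding used for base-frame fitting; the same templates are used by the
# duplex builder, so builder and measurer are exact inverses by construction.

BASE_TEMPLATES <- list(
  A = list(
    atoms = c("C1'", "N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3", "C4"),
    coords = matrix(c(
      -2.479, 5.346, 0,
      -1.291, 4.498, 0,
       0.024, 4.897, 0,
       0.877, 3.902, 0,
       0.071, 2.771, 0,
       0.369, 1.398, 0,
       1.611, 0.909, 0,
      -0.668, 0.532, 0,
      -2.035, 1.023, 0,
      -2.525, 2.252, 0,
      -1.474, 3.097, 0), ncol = 3, byrow = TRUE),
    glyc = "N9", ring = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4")
  ),
  G = list(
    atoms = c("C1'", "N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2", "N3", "C4"),
    coords = matrix(c(
      -2.477, 5.399, 0,
      -1.289, 4.551, 0,
       0.023, 4.962, 0,
       0.870, 3.969, 0,
       0.071, 2.833, 0,
       0.424, 1.460, 0,
       1.554, 0.955, 0,
      -0.700, 0.641, 0,
      -1.999, 1.087, 0,
      -2.949, 0.139, 0,
      -2.342, 2.364, 0,
      -1.265, 3.177, 0), ncol = 3, byrow = TRUE),
    glyc = "N9", ring = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4")
  ),
  C = list(
    atoms = c("C1'", "N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6"),
    coords = matrix(c(
      -2.477, 5.402, 0,
      -1.285, 4.542, 0,
      -1.472, 3.158, 0,
      -2.628, 2.709, 0,
      -0.391, 2.344, 0,
       0.837, 2.868, 0,
       1.875, 2.027, 0,
       1.056, 4.275, 0,
      -0.023, 5.068, 0), ncol = 3, byrow = TRUE),
    glyc = "N1", ring = c("N1", "C2", "N3", "C4", "C5", "C6")
  ),
  T = list(
    atoms = c("C1'", "N1", "C2", "O2", "N3", "C4", "O4", "C5", "C7", "C6"),
    coords = matrix(c(
      -2.481, 5.354, 0,
      -1.284, 4.500, 0,
      -1.462, 3.135, 0,
      -2.562, 2.608, 0,
      -0.298, 2.407, 0,
       0.994, 2.897, 0,
       1.944, 2.119, 0,
       1.106, 4.338, 0,
       2.466, 4.961, 0,
      -0.024, 5.057, 0), ncol = 3, byrow = TRUE),
    glyc = "N1", ring = c("N1", "C2", "N3", "C4", "C5", "C6")
  ),
  U = list(
    atoms = c("C1'", "N1", "C2", "O2", "N3", "C4", "O4", "C5", "C6"),
    coords = matrix(c(
      -2.481, 5.354, 0,
      -1.284, 4.500, 0,
      -1.462, 3.131, 0,
      -2.563, 2.608, 0,
      -0.302, 2.397, 0,
       0.989, 2.884, 0,
       1.935, 2.094, 0,
       1.089, 4.311, 0,
      -0.024, 5.053, 0), ncol = 3, byrow = TRUE),
    glyc = "N1", ring = c("N1", "C2", "N3", "C4", "C5", "C6")
  )
)

WC_COMPLEMENT <- c(A = "T", T = "A", G = "C", C = "G", U = "A")
WC_COMPLEMENT_RNA <- c(A = "U", U = "A", G = "C", C = "G")

base_code_from_resname <- function(resname) {
  rn <- normalize_resname(resname)
  map <- c(DA = "A", DG = "G", DC = "C", DT = "T", DU = "U",
           A = "A", G = "G", C = "C", U = "U",
           RA = "A", RG = "G", RC = "C", RU = "U",
           ADE = "A", GUA = "G", CYT = "C", THY = "T", URA = "U")
  unname(map[rn])
}

# Sugar-phosphate internal-coordinate sets (torsions in the package's own
# dihedral convention).  The values are calibrated once, per form preset, so
# that the sugar ring closes (C4'-O4' = 1.45 A) and the strand chains with
# an O3'(i)-P(i+1) distance of 1.60 A under the preset step transform
# (alpha_ref is the resulting C5'-O5'-P-O3'(i-1) torsion; OP1/OP2 are
# staggered +/-120 deg from it)
# (B: twist 36.0 deg / rise 3.38 A; A: twist 32.7 deg / roll 8 deg /
# rise 2.81 A / x-displacement -4 A), placing the phosphorus at a B-DNA-like
# 8.95 A helical radius.  They are geometric conventions of the synthetic
# builder, not fitted to any experimental structure.
SUGAR_PARAMS <- list(
  B = list(chi = 106.68, nu1 = -22.56, nu2 = 33.36,
           delta = -129.97, gamma = -44.44, beta = -142.06, alpha_ref = -1.11),
  A = list(chi = 105.61, nu1 = -25.89, nu2 = 33.08,
           delta = -127.59, gamma = -44.41, beta = -142.97, alpha_ref = -64.82)
)

# Full-nucleotide template (base + sugar + 5'-phosphate) in the standard base
# frame.  The sugar is built from internal coordinates with NeRF placement.
nucleotide_template <- function(base, form = c("B", "A"), o2prime = (form == "A"),
                                hydrogens = FALSE) {
  form <- match.arg(form)
  bt <- BASE_TEMPLATES[[base]]
  sp <- SUGAR_PARAMS[[form]]

  pos <- stats::setNames(
    lapply(seq_along(bt$atoms), function(i) bt$coords[i, ]), bt$atoms)
  glyc <- pos[[bt$glyc]]
  cref <- pos[[if (bt$glyc == "N9") "C4" else "C2"]]
  c1p <- pos[["C1'"]]

  pos[["O4'"]] <- place_atom(cref, glyc, c1p, 1.417, 108.2, sp$chi)
  pos[["C2'"]] <- place_atom(cref, glyc, c1p, 1.521, 114.0, sp$chi + 120)
  pos[["C3'"]] <- place_atom(pos[["O4'"]], c1p, pos[["C2'"]],
                             1.523, 102.5, sp$nu1)
  pos[["C4'"]] <- place_atom(c1p, pos[["C2'"]], pos[["C3'"]],
                             1.526, 102.7, sp$nu2)
  pos[["O3'"]] <- place_atom(c1p, pos[["C2'"]], pos[["C3'"]],
                             1.423, 110.0, sp$nu2 - 122)
  pos[["C5'"]] <- place_atom(pos[["O3'"]], pos[["C3'"]], pos[["C4'"]],
                             1.510, 114.7, sp$delta)
  pos[["O5'"]] <- place_atom(pos[["C3'"]], pos[["C4'"]], pos[["C5'"]],
                             1.440, 110.2, sp$gamma)
  pos[["P"]]   <- place_atom(pos[["C4'"]], pos[["C5'"]], pos[["O5'"]],
                             1.593, 120.9, sp$beta)
  pos[["OP1"]] <- place_atom(pos[["C5'"]], pos[["O5'"]], pos[["P"]],
                             1.485, 110.0, sp$alpha_ref + 120)
  pos[["OP2"]] <- place_atom(pos[["C5'"]], pos[["O5'"]], pos[["P"]],
                             1.485, 110.0, sp$alpha_ref - 120)
  if (o2prime) {
    pos[["O2'"]] <- place_atom(pos[["O4'"]], c1p, pos[["C2'"]],
                               1.413, 110.0, sp$nu1 + 122)
  }
  if (hydrogens) pos <- c(pos, base_hydrogens(base, pos))
  names <- names(pos)
  tibble::tibble(
    name = names,
    element = substr(sub("^[0-9']*", "", names), 1, 1),
    x = vapply(pos, `[`, 1, i = 1),
    y = vapply(pos, `[`, 1, i = 2),
    z = vapply(pos, `[`, 1, i = 3))
}

# In-plane hydrogens on nucleobase ring atoms and exocyclic amino/methyl
# groups; used when the builder is asked for hydrogens.
base_hydrogens <- function(base, pos) {
  h <- list()
  ring_h <- list(
    A = list(H8 = c("C8", "N9", "N7"), H2 = c("C2", "N1", "N3")),
    G = list(H8 = c("C8", "N9", "N7"), H1 = c("N1", "C2", "C6")),
    C = list(H6 = c("C6", "N1", "C5"), H5 = c("C5", "C4", "C6")),
    T = list(H6 = c("C6", "N1", "C5"), H3 = c("N3", "C2", "C4")),
    U = list(H6 = c("C6", "N1", "C5"), H5 = c("C5", "C4", "C6"),
             H3 = c("N3", "C2", "C4"))
  )[[base]]
  for (nm in names(ring_h)) {
    spec <- ring_h[[nm]]
    x <- pos[[spec[1]]]
    d <- unit3(2 * x - pos[[spec[2]]] - pos[[spec[3]]])
    h[[nm]] <- x + 1.01 * d
  }
  amino <- list(A = c("N6", "C6"), G = c("N2", "C2"), C = c("N4", "C4"))[[base]]
  if (!is.null(amino)) {
    n <- pos[[amino[1]]]; cc <- pos[[amino[2]]]
    axis <- c(0, 0, 1)
    d0 <- unit3(n - cc)
    lab <- paste0("H", substr(amino[1], 2, 2), 1:2)
    # H-N-C angle ~120 deg: hydrogens at +/-60 deg from the C->N extension
    h[[lab[1]]] <- n + 1.01 * as.numeric(rot_axis(axis, 60) %*% d0)
    h[[lab[2]]] <- n + 1.01 * as.numeric(rot_axis(axis, -60) %*% d0)
  }
  if (base == "T") {
    c7 <- pos[["C7"]]; c5 <- pos[["C5"]]
    d0 <- unit3(c7 - c5)
    perp <- unit3(cross3(d0, c(0, 0, 1)))
    for (k in 1:3) {
      rot <- rot_axis(d0, 120 * (k - 1))
      dir <- as.numeric(rot %*% (0.5 * d0 + 0.866 * c(0, 0, 1)))
      h[[paste0("H7", k)]] <- c7 + 1.09 * unit3(dir)
    }
  }
  h
}

# Bundled toy parameter table for synthetic systems.  The phosphate group
# (P, OP1, OP2) carries net charge -1 e; every other nucleic atom is neutral,
# so a parameterized strand has net charge -(number of phosphates).  Probe
# residues carry unit positive charge on their cationic nitrogens.
LJ_BY_ELEMENT <- list(
  C = c(3.40, 0.086), N = c(3.25, 0.170), O = c(2.96, 0.210),
  P = c(3.74, 0.200), H = c(1.00, 0.0157), S = c(3.56, 0.250)
)

#' Bundled parameter table for synthetic systems
#'
#' Builds the flat (residue name, atom name) parameter table covering every
#' atom the synthetic generators emit: masses from the element, element-wise
#' Lennard-Jones parameters, and a minimal charge model (phosphate group
#' -1 e split as P +1.10, OP1/OP2 -1.05 each; Lys NZ +1 e; Arg NH1/NH2
#' +0.5 e each; all other atoms neutral).
#'
#' @param system A [mol_system] listing the (residue, atom) pairs to cover.
#' @return A parameter-table tibble (see [read_parameter_table()]).
#' @export
synthetic_parameter_table <- function(system) {
  a <- system$atoms
  key <- unique(paste(normalize_resname(a$resname), a$name, a$element,
                      sep = "|"))
  parts <- strsplit(key, "|", fixed = TRUE)
  resname <- vapply(parts, `[`, "", 1)
  atom <- vapply(parts, `[`, "", 2)
  element <- vapply(parts, `[`, "", 3)
  lj <- t(vapply(element, function(e) {
    p <- LJ_BY_ELEMENT[[e]]
    if (is.null(p)) c(3.4, 0.1) else p
  }, numeric(2)))
  charge <- rep(0, length(atom))
  charge[atom == "P"] <- 1.10
  charge[atom %in% c("OP1", "OP2")] <- -1.05
  charge[resname == "LYS" & atom == "NZ"] <- 1.0
  charge[resname == "ARG" & atom %in% c("NH1", "NH2")] <- 0.5
  tibble::tibble(
    resname = resname, atom = atom,
    mass = unname(lookup_element_value(ELEMENT_MASSES, element, 12.011)),
    charge = charge, sigma = unname(lj[, 1]), epsilon = unname(lj[, 2]))
}
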