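#' Molecular system (topology) container
#'
#' A `mol_system` holds the topology of a molecular system: one row per atom
#' with residue and chain identity, element, role classification and (once
#' loaded) mass, partial charge and Lennard-Jones parameters.  Coordinates
#' live in a separate frame matrix or a [traj_ensemble].
#'
#' @param atoms A data frame with columns `name`, `element`, `resname`,
#'   `resid`, `chain` (one row per atom, file order).  Optional columns
#'   `mass`, `charge`, `lj_sigma`, `lj_epsilon`, `role` are carried along.
#' @param bonds Optional two-column integer matrix of bonded atom-index pairs.
#'
#' @return An object of class `mol_system`: a list with elements `atoms`
#'   (tibble, one row per atom), `residues` (tibble, one row per residue with
#'   `res_index`, `resname`, `resid`, `chain`, `polymer`), `bonds`.
#' @export
mol_system <- function(atoms, bonds = NULL) {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0)
  need <- c("name", "element", "resname", "resid", "chain")
  missing <- setdiff(need, names(atoms))
  if (length(missing) > 0) {
    stop("atoms table lacks column(s): ", paste(missing, collapse = ", "))
  }
  atoms <- tibble::as_tibble(atoms)
  atoms$name    <- normalize_atom_name(atoms$name)
  atoms$element <- toupper(trimws(atoms$element))
  # dense residue index in order of first appearance
  res_key <- paste(atoms$chain, atoms$resid, atoms$resname, sep = "|")
  res_index <- match(res_key, unique(res_key))
  atoms$res_index <- res_index
  first <- !duplicated(res_index)
  residues <- tibble::tibble(
    res_index = res_index[first],
    resname   = atoms$resname[first],
    resid     = atoms$resid[first],
    chain     = atoms$chain[first],
    polymer   = polymer_kind(atoms$resname[first])
  )
  for (col in c("mass", "charge", "lj_sigma", "lj_epsilon")) {
    if (is.null(atoms[[col]])) atoms[[col]] <- NA_real_
  }
  if (is.null(atoms[["role"]])) atoms[["role"]] <- NA_character_
  atoms$is_heavy <- atoms$element != "H"
  structure(
    list(atoms = atoms, residues = residues, bonds = bonds),
    class = "mol_system"
  )
}

#' Polymer kind from residue names
#'
#' Classifies residue names as `protein`, `nucleic` or `other` using standard
#' residue-name tables (terminal `5`/`3` suffixes are accepted).
#'
#' @param resname Character vector of residue names.
#' @return Character vector, same length, in `{protein, nucleic, other}`.
#' @export
polymer_kind <- function(resname) {
  rn <- normalize_resname(resname)
  out <- rep("other", length(rn))
  out[rn %in% PROTEIN_RESNAMES] <- "protein"
  out[rn %in% NUCLEIC_RESNAMES] <- "nucleic"
  out
}

#' @export
print.mol_system <- function(x, ...) {
  cat("<mol_system> ", n_atoms(x), " atoms, ", nrow(x$residues), " residues (",
      paste(sprintf("%s: %d", names(table(x$residues$polymer)),
                    as.integer(table(x$residues$polymer))), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Number of atoms in a system
#' @param system A [mol_system].
#' @return Integer atom count.
#' @export
n_atoms <- function(system) nrow(system$atoms)

#' Atom table of a system as a tibble
#' @param x A [mol_system].
#' @param ... Unused.
#' @method as_tibble mol_system
#' @export
as_tibble.mol_system <- function(x, ...) x$atoms

#' Select atoms of a system
#'
#' Builds an atom selection (sorted unique 1-based indices) from simple
#' predicates over the atom table.  All supplied conditions are ANDed.
#'
#' @param system A [mol_system].
#' @param polymer Optional polymer kind(s) (`"protein"`, `"nucleic"`, `"other"`).
#' @param role Optional role label(s), see [classify_atoms()].
#' @param elety Optional atom name(s).
#' @param resname,chain,res_index Optional residue filters.
#' @param heavy If `TRUE`, keep heavy atoms only.
#' @return An `atom_selection`: integer vector of atom indices with a
#'   `provenance` attribute describing the query.
#' @export
select_atoms <- function(system, polymer = NULL, role = NULL, elety = NULL,
                         resname = NULL, chain = NULL, res_index = NULL,
                         heavy = FALSE) {
  a <- system$atoms
  keep <- rep(TRUE, nrow(a))
  prov <- character(0)
  if (!is.null(polymer)) {
    pk <- system$residues$polymer[a$res_index]
    keep <- keep & pk %in% polymer
    prov <- c(prov, paste0("polymer=", paste(polymer, collapse = "/")))
  }
  if (!is.null(role)) {
    if (all(is.na(a$role))) stop("roles not set; run classify_atoms() first")
    keep <- keep & a$role %in% role
    prov <- c(prov, paste0("role=", paste(role, collapse = "/")))
  }
  if (!is.null(elety)) {
    keep <- keep & a$name %in% normalize_atom_name(elety)
    prov <- c(prov, paste0("name=", paste(elety, collapse = "/")))
  }
  if (!is.null(resname)) {
    keep <- keep & normalize_resname(a$resname) %in% normalize_resname(resname)
    prov <- c(prov, paste0("resname=", paste(resname, collapse = "/")))
  }
  if (!is.null(chain)) {
    keep <- keep & a$chain %in% chain
    prov <- c(prov, paste0("chain=", paste(chain, collapse = "/")))
  }
  if (!is.null(res_index)) {
    keep <- keep & a$res_index %in% res_index
    prov <- c(prov, "res_index subset")
  }
  if (heavy) {
    keep <- keep & a$is_heavy
    prov <- c(prov, "heavy")
  }
  atom_selection(which(keep), paste(prov, collapse = " & "))
}

#' Construct an atom selection from indices
#'
#' @param indices Integer atom indices (1-based).
#' @param provenance Free-text description of how the selection was built.
#' @return An `atom_selection` object.
#' @export
atom_selection <- function(indices, provenance = "manual") {
  idx <- sort(unique(as.integer(indices)))
  if (any(is.na(idx)) || any(idx < 1)) stop("invalid atom indices in selection")
  structure(idx, provenance = provenance, class = c("atom_selection", "integer"))
}

#' @export
print.atom_selection <- function(x, ...) {
  cat("<atom_selection> ", length(x), " atoms [",
      attr(x, "provenance"), "]\n", sep = "")
  invisible(x)
}

validate_selection <- function(system, selection) {
  idx <- as.integer(selection)
  if (length(idx) == 0) stop("empty atom selection")
  if (any(idx < 1 | idx > n_atoms(system))) {
    stop("selection indices out of range for system with ",
         n_atoms(system), " atoms")
  }
  idx
}

#' Trajectory container
#'
#' A `traj_ensemble` stores an ordered set of coordinate frames for a fixed
#' topology, bio3d-style: one row per frame, columns `(x1, y1, z1, x2, ...)`.
#'
#' @param system The linked [mol_system].
#' @param xyz Numeric matrix, `n_frames x (3 * n_atoms)`.
#' @param times Frame times in ps; defaults to 1 ps spacing starting at 1 ps.
#' @return An object of class `traj_ensemble`.
#' @export
traj_ensemble <- function(system, xyz, times = NULL) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3 * n_atoms(system)) {
    stop("xyz has ", ncol(xyz), " columns; expected ", 3 * n_atoms(system))
  }
  if (!all(is.finite(xyz))) stop("non-finite coordinates in trajectory")
  if (is.null(times)) times <- seq_len(nrow(xyz)) * 1.0
  if (length(times) != nrow(xyz)) stop("times length must equal frame count")
  if (nrow(xyz) > 1 && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing")
  }
  structure(list(system = system, xyz = xyz, times = as.numeric(times)),
            class = "traj_ensemble")
}

#' @export
print.traj_ensemble <- function(x, ...) {
  cat("<traj_ensemble> ", n_frames(x), " frames x ", n_atoms(x$system),
      " atoms; t = [", x$times[1], ", ", x$times[n_frames(x)], "] ps\n",
      sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A [traj_ensemble].
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Extract one frame as an N x 3 coordinate matrix
#' @param traj A [traj_ensemble].
#' @param i Frame index.
#' @export
frame_coords <- function(traj, i) {
  if (i < 1 || i > n_frames(traj)) stop("frame index out of range")
  xyz_to_coords(traj$xyz[i, ])
}

# flat xyz row <-> N x 3 matrix
xyz_to_coords <- function(v) matrix(v, ncol = 3, byrow = TRUE)
coords_to_xyz <- function(m) as.numeric(t(m))

#' Drop an initial equilibration segment from a trajectory
#'
#' Frames with time strictly greater than `t_cut` are retained; the input is
#' untouched.  The conventional production setting discards the first 100 ns
#' (100000 ps) of each run as equilibration.
#'
#' @param traj A [traj_ensemble].
#' @param t_cut Equilibration cut time in ps.
#' @return A new [traj_ensemble] with the remaining frames.
#' @export
discard_equilibration <- function(traj, t_cut) {
  if (t_cut >= max(traj$times)) {
    stop("t_cut (", t_cut, " ps) leaves no frames: last time is ",
         max(traj$times), " ps")
  }
  keep <- traj$times > t_cut
  traj_ensemble(traj$system, traj$xyz[keep, , drop = FALSE], traj$times[keep])
}
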