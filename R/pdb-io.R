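#' Read a single-structure PDB file
#'
#' Parses a PDB v3.3 file (via bio3d) into a [mol_system] plus one coordinate
#' frame.  Reading never invents physics: charges and Lennard-Jones
#' parameters stay unset until [load_parameters()] is called.
#'
#' @param path Path to a PDB file.
#' @param format Input format; only `"pdb"` is supported.
#' @param infer_bonds If `TRUE` (default), bonds are inferred from covalent
#'   radii on the first frame (needed by the contact detectors).
#' @return A list with elements `system` ([mol_system]), `coords`
#'   (`n_atoms x 3` matrix, Angstrom).
#' @export
read_structure <- function(path, format = c("pdb"), infer_bonds = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
    error = function(e) stop("PDB parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (nrow(pdb$atom) == 0) stop("empty input: no ATOM/HETATM records in ", path)
  system <- system_from_bio3d(pdb)
  coords <- xyz_to_coords(pdb$xyz[1, ])
  other <- system$residues$resname[system$residues$polymer == "other"]
  if (length(other) > 0) {
    warning("residue(s) with unknown polymer kind set to 'other': ",
            paste(unique(other), collapse = ", "))
  }
  if (infer_bonds) system$bonds <- infer_bonds(system, coords)
  list(system = system, coords = coords)
}

system_from_bio3d <- function(pdb) {
  a <- pdb$atom
  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem)) || all(trimws(elem) == "")) {
    elem <- guess_element(a$elety)
  } else {
    blank <- is.na(elem) | trimws(elem) == ""
    elem[blank] <- guess_element(a$elety[blank])
  }
  chain <- a$chain
  chain[is.na(chain) | chain == ""] <- "A"
  mol_system(data.frame(
    name = a$elety, element = toupper(trimws(elem)),
    resname = a$resid, resid = a$resno, chain = chain,
    stringsAsFactors = FALSE
  ))
}

# Element symbol from a PDB atom name (columns 77-78 absent).
guess_element <- function(name) {
  nm <- normalize_atom_name(name)
  # two-letter ions/metals first
  two <- substr(nm, 1, 2)
  out <- ifelse(two %in% c("ZN", "MG", "CL", "NA", "FE", "MN", "BR"),
                two, NA_character_)
  first_alpha <- sub("^[0-9']*", "", nm)
  out[is.na(out)] <- substr(first_alpha[is.na(out)], 1, 1)
  out
}

#' Read a multi-model PDB trajectory
#'
#' Each MODEL of the file becomes one frame.  Atom counts are checked per
#' model against the topology before parsing proceeds.
#'
#' @param path Path to a multi-model PDB file.
#' @param topology A [mol_system] describing the expected atoms.
#' @param format Only `"multi_model_pdb"` is supported natively.
#' @param times Frame times (ps); default assigns 1 ps spacing.
#' @return A [traj_ensemble].
#' @export
read_trajectory <- function(path, topology,
                            format = c("multi_model_pdb"), times = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  check_model_atom_counts(path, n_atoms(topology))
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3 * n_atoms(topology)) {
    stop("trajectory atom count (", ncol(xyz) / 3,
         ") does not match topology (", n_atoms(topology), ")")
  }
  traj_ensemble(topology, xyz, times)
}

# Pre-scan MODEL blocks so an atom-count mismatch names the offending model.
check_model_atom_counts <- function(path, expected) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_starts <- grepl("^MODEL", lines)
  if (!any(model_starts)) {
    count <- sum(is_atom)
    if (count != expected) {
      stop("model 1: ", count, " atoms, expected ", expected)
    }
    return(invisible(1L))
  }
  model_id <- cumsum(model_starts)
  counts <- tapply(is_atom[model_id > 0], model_id[model_id > 0], sum)
  bad <- which(counts != expected)
  if (length(bad) > 0) {
    k <- bad[1]
    stop("model ", k, ": ", counts[k], " atoms, expected ", expected)
  }
  invisible(length(counts))
}

format_pdb_atom_line <- function(serial, name, resname, chain, resid, xyz,
                                 element) {
  # PDB alignment rule: names shorter than 4 chars start in column 14
  nm <- ifelse(nchar(name) >= 4, substr(name, 1, 4), sprintf(" %-3s", name))
  sprintf("ATOM  %5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000, nm, substr(resname, 1, 4), substr(chain, 1, 1),
          resid %% 10000, xyz[1], xyz[2], xyz[3], 1.0, 0.0,
          substr(element, 1, 2))
}

#' Write a structure (or trajectory) as (multi-model) PDB
#'
#' @param system A [mol_system].
#' @param coords Either an `n_atoms x 3` matrix (single structure) or a
#'   [traj_ensemble] / `n_frames x 3N` matrix (multi-model output).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(system, coords, path) {
  a <- system$atoms
  if (inherits(coords, "traj_ensemble")) coords <- coords$xyz
  if (is.matrix(coords) && ncol(coords) == 3 && nrow(coords) == n_atoms(system)) {
    coords <- matrix(coords_to_xyz(coords), nrow = 1)
  }
  stopifnot(ncol(coords) == 3 * n_atoms(system))
  con <- file(path, "w")
  on.exit(close(con))
  multi <- nrow(coords) > 1
  for (f in seq_len(nrow(coords))) {
    if (multi) writeLines(sprintf("MODEL     %4d", f), con)
    m <- xyz_to_coords(coords[f, ])
    lines <- vapply(seq_len(nrow(a)), function(i) {
      format_pdb_atom_line(i, a$name[i], a$resname[i], a$chain[i],
                           a$resid[i], m[i, ], a$element[i])
    }, character(1))
    writeLines(lines, con)
    writeLines(if (multi) "ENDMDL" else "TER", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Infer covalent bonds from interatomic distances
#'
#' Two atoms are bonded if their distance is below the sum of their covalent
#' radii plus 0.45 A (capped at 1.25 A for bonds involving hydrogen).  Only
#' atoms within the same or in residue-index-adjacent residues are examined.
#'
#' @param system A [mol_system].
#' @param coords `n_atoms x 3` coordinate matrix.
#' @return Two-column integer matrix of bonded atom index pairs (i < j).
#' @export
infer_bonds <- function(system, coords) {
  a <- system$atoms
  n <- nrow(a)
  radii <- lookup_element_value(COVALENT_RADII, a$element, 0.77)
  bonds <- vector("list", n)
  ord <- order(a$res_index)
  # candidate pairs restricted to same/adjacent residues
  pairs_i <- integer(0); pairs_j <- integer(0)
  for (ri in unique(a$res_index)) {
    idx <- which(a$res_index %in% c(ri, ri + 1L))
    own <- which(a$res_index[idx] == ri)
    if (length(idx) < 2) next
    cmb <- expand.grid(i = idx[own], j = idx)
    cmb <- cmb[cmb$i < cmb$j, , drop = FALSE]
    pairs_i <- c(pairs_i, cmb$i); pairs_j <- c(pairs_j, cmb$j)
  }
  if (length(pairs_i) == 0) return(matrix(integer(0), ncol = 2))
  d <- sqrt(rowSums((coords[pairs_i, , drop = FALSE] -
                     coords[pairs_j, , drop = FALSE])^2))
  cut <- radii[pairs_i] + radii[pairs_j] + 0.45
  has_h <- a$element[pairs_i] == "H" | a$element[pairs_j] == "H"
  cut[has_h] <- pmin(cut[has_h], 1.25)
  hh <- a$element[pairs_i] == "H" & a$element[pairs_j] == "H"
  keep <- d <= cut & d > 0.4 & !hh
  cbind(i = pairs_i[keep], j = pairs_j[keep])
}

bonded_neighbors <- function(system, atom) {
  b <- system$bonds
  if (is.null(b)) stop("system has no bonds; run infer_bonds() first")
  c(b[b[, 1] == atom, 2], b[b[, 2] == atom, 1])
}
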