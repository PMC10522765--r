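#' Geometric contact criteria
#'
#' Thresholds for the three scored contact types.  Defaults are mainstream
#' MD-analysis values: donor-acceptor distance 3.5 A with donor-H-acceptor
#' angle >= 135 deg for hydrogen bonds, N...O distance 4.0 A for salt
#' bridges, C...C distance 4.5 A for apolar contacts.
#'
#' @param hbond_da_max Hydrogen-bond donor-acceptor distance cutoff (A).
#' @param hbond_dha_min Minimum donor-H-acceptor angle (deg, in (0, 180]).
#' @param salt_no_max Salt-bridge N...O distance cutoff (A).
#' @param apolar_cc_max Apolar C...C distance cutoff (A).
#' @param his_protonated Treat histidine as protonated (salt-bridge capable);
#'   default `FALSE` (neutral).
#' @return A `contact_criteria` list.
#' @export
contact_criteria <- function(hbond_da_max = 3.5, hbond_dha_min = 135,
                             salt_no_max = 4.0, apolar_cc_max = 4.5,
                             his_protonated = FALSE) {
  stopifnot(hbond_da_max > 0, salt_no_max > 0, apolar_cc_max > 0,
            hbond_dha_min > 0, hbond_dha_min <= 180)
  structure(list(hbond_da_max = hbond_da_max, hbond_dha_min = hbond_dha_min,
                 salt_no_max = salt_no_max, apolar_cc_max = apolar_cc_max,
                 his_protonated = his_protonated),
            class = "contact_criteria")
}

#' Classify a contact as specific or nonspecific
#'
#' A contact is specific iff the protein atom is a side-chain atom AND the
#' nucleic atom is a nucleobase atom; every contact touching either backbone
#' is nonspecific.  Atoms with role `other` yield `NA` with a warning (such
#' events are ignored by the map builder).
#'
#' @param system A classified [mol_system].
#' @param protein_atom,nucleic_atom Atom indices.
#' @return Character vector in `{specific, nonspecific}` (or `NA`).
#' @export
classify_contact <- function(system, protein_atom, nucleic_atom) {
  rp <- system$atoms$role[protein_atom]
  rn <- system$atoms$role[nucleic_atom]
  out <- ifelse(rp == "protein_sidechain" & rn == "base",
                "specific", "nonspecific")
  bad <- rp == "other" | rn == "other"
  if (any(bad)) {
    warning("contact(s) involving role 'other' atoms ignored")
    out[bad] <- NA_character_
  }
  out
}

# ---- candidate enumeration (topology-dependent, frame-independent) ----------

# donors: N/O with at least one bonded H; returns donor/H pairs
polar_donors <- function(system, atom_pool) {
  a <- system$atoms
  b <- system$bonds
  if (is.null(b)) stop("system has no bonds; contact detection needs bonds")
  h_i <- b[a$element[b[, 2]] == "H", , drop = FALSE]
  h_j <- b[a$element[b[, 1]] == "H", , drop = FALSE]
  don <- rbind(cbind(donor = h_i[, 1], h = h_i[, 2]),
               cbind(donor = h_j[, 2], h = h_j[, 1]))
  keep <- a$element[don[, "donor"]] %in% c("N", "O") &
    don[, "donor"] %in% atom_pool
  don[keep, , drop = FALSE]
}

polar_acceptors <- function(system, atom_pool) {
  a <- system$atoms
  atom_pool[a$element[atom_pool] %in% c("N", "O")]
}

# apolar atoms: carbons not covalently bonded to N or O
apolar_atoms <- function(system, atom_pool) {
  a <- system$atoms
  b <- system$bonds
  carbons <- atom_pool[a$element[atom_pool] == "C"]
  touches_no <- function(i) {
    nb <- bonded_neighbors(system, i)
    any(a$element[nb] %in% c("N", "O"))
  }
  carbons[!vapply(carbons, touches_no, logical(1))]
}

# cationic protein nitrogens (Arg NH1/NH2/NE, Lys NZ, His ND1/NE2 if protonated)
cationic_protein_atoms <- function(system, his_protonated = FALSE) {
  a <- system$atoms
  rn <- normalize_resname(a$resname)
  sel <- (rn == "ARG" & a$name %in% CATIONIC_ATOMS$ARG) |
    (rn == "LYS" & a$name %in% CATIONIC_ATOMS$LYS)
  if (his_protonated) {
    sel <- sel | (rn %in% c("HIS", "HIP") & a$name %in% CATIONIC_ATOMS$HIS_PROTONATED)
  }
  which(sel)
}

# anionic nucleic oxygens: oxygens covalently bonded to a phosphorus
anionic_nucleic_atoms <- function(system, atom_pool) {
  a <- system$atoms
  ox <- atom_pool[a$element[atom_pool] == "O"]
  ox[vapply(ox, function(i) {
    any(a$element[bonded_neighbors(system, i)] == "P")
  }, logical(1))]
}

interface_pools <- function(system) {
  pro <- which(system$residues$polymer[system$atoms$res_index] == "protein")
  nuc <- which(system$residues$polymer[system$atoms$res_index] == "nucleic")
  if (length(pro) == 0 || length(nuc) == 0) {
    stop("system needs both protein and nucleic atoms for interface contacts")
  }
  list(protein = pro, nucleic = nuc)
}

# Full candidate table for all three detectors.  Each row is a potential
# atom-level event; hydrogens attached to a donor are kept in a list column.
contact_candidates <- function(system, criteria) {
  pools <- interface_pools(system)
  a <- system$atoms
  out <- list()

  # hydrogen bonds, both donor directions
  for (dir in c("p2n", "n2p")) {
    don_pool <- if (dir == "p2n") pools$protein else pools$nucleic
    acc_pool <- if (dir == "p2n") pools$nucleic else pools$protein
    don <- polar_donors(system, don_pool)
    acc <- polar_acceptors(system, acc_pool)
    if (nrow(don) > 0 && length(acc) > 0) {
      donors <- unique(don[, "donor"])
      grid <- expand.grid(donor = donors, acceptor = acc)
      hs <- lapply(grid$donor, function(d) unname(don[don[, "donor"] == d, "h"]))
      prot <- if (dir == "p2n") grid$donor else grid$acceptor
      nucl <- if (dir == "p2n") grid$acceptor else grid$donor
      out[[dir]] <- tibble::tibble(
        type = "hbond", protein_atom = as.integer(prot),
        nucleic_atom = as.integer(nucl),
        donor = as.integer(grid$donor), acceptor = as.integer(grid$acceptor),
        hydrogens = hs)
    }
  }

  cat_at <- intersect(cationic_protein_atoms(system, criteria$his_protonated),
                      pools$protein)
  an_at <- anionic_nucleic_atoms(system, pools$nucleic)
  if (length(cat_at) > 0 && length(an_at) > 0) {
    grid <- expand.grid(cation = cat_at, anion = an_at)
    out$salt <- tibble::tibble(
      type = "salt_bridge", protein_atom = as.integer(grid$cation),
      nucleic_atom = as.integer(grid$anion),
      donor = NA_integer_, acceptor = NA_integer_,
      hydrogens = vector("list", nrow(grid)))
  }

  ap_p <- apolar_atoms(system, pools$protein)
  ap_n <- apolar_atoms(system, pools$nucleic)
  if (length(ap_p) > 0 && length(ap_n) > 0) {
    grid <- expand.grid(p = ap_p, n = ap_n)
    out$apolar <- tibble::tibble(
      type = "apolar", protein_atom = as.integer(grid$p),
      nucleic_atom = as.integer(grid$n),
      donor = NA_integer_, acceptor = NA_integer_,
      hydrogens = vector("list", nrow(grid)))
  }

  cand <- dplyr::bind_rows(out)
  if (nrow(cand) == 0) return(cand)
  cand$class <- classify_contact(system, cand$protein_atom, cand$nucleic_atom)
  cand[!is.na(cand$class), , drop = FALSE]
}

# presence of every candidate event in one frame (logical vector)
candidate_presence <- function(cand, coords, criteria) {
  if (nrow(cand) == 0) return(logical(0))
  d <- sqrt(rowSums((coords[cand$protein_atom, , drop = FALSE] -
                     coords[cand$nucleic_atom, , drop = FALSE])^2))
  pres <- logical(nrow(cand))
  is_h <- cand$type == "hbond"
  is_s <- cand$type == "salt_bridge"
  is_a <- cand$type == "apolar"
  pres[is_s] <- d[is_s] <= criteria$salt_no_max
  pres[is_a] <- d[is_a] <= criteria$apolar_cc_max
  hb <- which(is_h & d <= criteria$hbond_da_max)
  for (k in hb) {
    dpos <- coords[cand$donor[k], ]
    apos <- coords[cand$acceptor[k], ]
    for (h in cand$hydrogens[[k]]) {
      v1 <- dpos - coords[h, ]
      v2 <- apos - coords[h, ]
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
      if (ang >= criteria$hbond_dha_min) { pres[k] <- TRUE; break }
    }
  }
  pres
}

#' Detect interfacial hydrogen bonds in one frame
#'
#' A bond exists iff the donor-acceptor distance is at most `hbond_da_max`
#' and the donor-H-acceptor angle is at least `hbond_dha_min` for some
#' hydrogen bonded to the donor.  Donors and acceptors are N/O atoms typed
#' from element and bonding; donors without hydrogens are skipped (they
#' cannot form a detectable bond).  Only protein-nucleic pairs are reported.
#'
#' @param coords `n_atoms x 3` frame coordinates.
#' @param system A classified [mol_system] with bonds.
#' @param criteria A [contact_criteria].
#' @return Tibble with columns `donor`, `acceptor`, `protein_atom`,
#'   `nucleic_atom`, `class`.
#' @export
detect_hbonds <- function(coords, system, criteria = contact_criteria()) {
  if (!any(system$atoms$element == "H")) {
    warning("system has no hydrogens: all potential donors skipped ",
            "(hydrogen bonds need explicit hydrogens)")
  }
  cand <- contact_candidates(system, criteria)
  empty <- tibble::tibble(donor = integer(0), acceptor = integer(0),
                          protein_atom = integer(0),
                          nucleic_atom = integer(0), class = character(0))
  if (nrow(cand) == 0) return(empty)
  cand <- cand[cand$type == "hbond", , drop = FALSE]
  if (nrow(cand) == 0) return(empty)
  pres <- candidate_presence(cand, coords, criteria)
  res <- cand[pres, c("donor", "acceptor", "protein_atom", "nucleic_atom",
                      "class")]
  tibble::as_tibble(res)
}

#' Detect interfacial salt bridges in one frame
#'
#' A bridge exists iff the distance between a cationic protein nitrogen
#' (Arg NH1/NH2/NE, Lys NZ, His ND1/NE2 when protonated) and an anionic
#' phosphate oxygen (any O bonded to P) is at most `salt_no_max`.  Salt
#' bridges to the phosphate are nonspecific by construction.
#'
#' @inheritParams detect_hbonds
#' @return Tibble with columns `cation`, `anion`, `protein_atom`,
#'   `nucleic_atom`, `class`.
#' @export
detect_salt_bridges <- function(coords, system, criteria = contact_criteria()) {
  cand <- contact_candidates(system, criteria)
  empty <- tibble::tibble(cation = integer(0), anion = integer(0),
                          protein_atom = integer(0),
                          nucleic_atom = integer(0), class = character(0))
  if (nrow(cand) == 0) return(empty)
  cand <- cand[cand$type == "salt_bridge", , drop = FALSE]
  if (nrow(cand) == 0) return(empty)
  pres <- candidate_presence(cand, coords, criteria)
  out <- cand[pres, c("protein_atom", "nucleic_atom", "class")]
  out$cation <- out$protein_atom
  out$anion <- out$nucleic_atom
  tibble::as_tibble(out[c("cation", "anion", "protein_atom", "nucleic_atom",
                          "class")])
}

#' Detect interfacial apolar (hydrophobic) contacts in one frame
#'
#' Apolar atoms are carbons not covalently bonded to N or O; a contact
#' exists iff a protein and a nucleic apolar carbon are within
#' `apolar_cc_max`.
#'
#' @inheritParams detect_hbonds
#' @return Tibble with columns `protein_atom`, `nucleic_atom`, `class`.
#' @export
detect_apolar <- function(coords, system, criteria = contact_criteria()) {
  cand <- contact_candidates(system, criteria)
  empty <- tibble::tibble(protein_atom = integer(0),
                          nucleic_atom = integer(0), class = character(0))
  if (nrow(cand) == 0) return(empty)
  cand <- cand[cand$type == "apolar", , drop = FALSE]
  if (nrow(cand) == 0) return(empty)
  pres <- candidate_presence(cand, coords, criteria)
  tibble::as_tibble(cand[pres, c("protein_atom", "nucleic_atom", "class")])
}

#' Dynamic contact map of a trajectory
#'
#' Implements the dynamic contact-map scoring: (1) the presence series of
#' every atom-level event (hydrogen bond, salt bridge, apolar contact) is
#' computed over all analysed frames; (2) events present in no more than
#' `persistence` of the frames are dropped (the production default keeps
#' contacts present for longer than 10\% of the trajectory); (3) for each
#' (protein residue, nucleic residue, class) the per-frame strength is the
#' number of surviving events simultaneously present, each contact type
#' contributing 1; (4) the mean and SD of that strength are taken over all
#' analysed frames, with frames where no event is present contributing 0.
#'
#' An atom pair qualifying as both hydrogen bond and salt bridge in a frame
#' is counted once, as a salt bridge.  SDs are reported both frame-wise
#' (population SD over frames) and block-wise (SD over `n_blocks` contiguous
#' block means).
#'
#' @param traj A [traj_ensemble] (equilibration already discarded).
#' @param criteria A [contact_criteria].
#' @param persistence Occupancy threshold; events with occupancy `<=`
#'   this fraction are dropped.  Default 0.10.
#' @param n_blocks Number of contiguous blocks for the block SD (default 5).
#' @return A `contact_map` object: list with `map` (residue-pair tibble:
#'   `protein_res`, `protein_resname`, `nucleic_res`, `nucleic_resname`,
#'   `class`, `mean_strength`, `sd`, `sd_block`, `n_events`), `events`
#'   (atom-level tibble with occupancies and the kept flag), `presence`
#'   (kept-event x frame logical matrix), `n_frames`, `criteria`,
#'   `persistence`.
#' @export
build_dynamic_contact_map <- function(traj, criteria = contact_criteria(),
                                      persistence = 0.10, n_blocks = 5) {
  system <- traj$system
  nf <- n_frames(traj)
  if (nf == 0) stop("empty trajectory")
  if (all(is.na(system$atoms$role))) {
    stop("roles not set; run classify_atoms() first")
  }
  cand <- contact_candidates(system, criteria)
  if (nrow(cand) == 0) {
    stop("no candidate contact events at the protein-nucleic interface")
  }
  pres <- matrix(FALSE, nrow = nrow(cand), ncol = nf)
  for (f in seq_len(nf)) {
    pres[, f] <- candidate_presence(cand, frame_coords(traj, f), criteria)
  }

  # tie-break: same heavy-atom pair present as both hbond and salt bridge
  # counts once, as the salt bridge (charge-charge dominates)
  pair_key <- paste(cand$protein_atom, cand$nucleic_atom)
  hb <- which(cand$type == "hbond")
  sb <- which(cand$type == "salt_bridge")
  if (length(hb) > 0 && length(sb) > 0) {
    m <- match(pair_key[hb], pair_key[sb])
    dup <- which(!is.na(m))
    for (k in dup) {
      pres[hb[k], ] <- pres[hb[k], ] & !pres[sb[m[k]], ]
    }
  }

  occ <- rowMeans(pres)
  cand$occupancy <- occ
  cand$kept <- occ > persistence
  atoms <- system$atoms
  cand$protein_res <- atoms$res_index[cand$protein_atom]
  cand$nucleic_res <- atoms$res_index[cand$nucleic_atom]

  kept <- which(cand$kept & cand$occupancy > 0)
  keymap <- tibble::tibble(
    protein_res = cand$protein_res[kept],
    nucleic_res = cand$nucleic_res[kept],
    class = cand$class[kept])
  groups <- unique(keymap)
  rows <- vector("list", nrow(groups))
  block_id <- cut(seq_len(nf), breaks = n_blocks, labels = FALSE)
  for (g in seq_len(nrow(groups))) {
    sel <- kept[keymap$protein_res == groups$protein_res[g] &
                keymap$nucleic_res == groups$nucleic_res[g] &
                keymap$class == groups$class[g]]
    strength <- colSums(pres[sel, , drop = FALSE])
    mu <- mean(strength)
    sd_frame <- sqrt(mean((strength - mu)^2))
    block_means <- tapply(strength, block_id, mean)
    rows[[g]] <- tibble::tibble(
      protein_res = groups$protein_res[g],
      nucleic_res = groups$nucleic_res[g],
      class = groups$class[g],
      mean_strength = mu, sd = sd_frame,
      sd_block = stats::sd(block_means),
      n_events = length(sel))
  }
  map <- if (length(rows) > 0) dplyr::bind_rows(rows) else tibble::tibble(
    protein_res = integer(0), nucleic_res = integer(0), class = character(0),
    mean_strength = numeric(0), sd = numeric(0), sd_block = numeric(0),
    n_events = integer(0))
  res <- system$residues
  map$protein_resname <- res$resname[map$protein_res]
  map$protein_resid <- res$resid[map$protein_res]
  map$nucleic_resname <- res$resname[map$nucleic_res]
  map$nucleic_resid <- res$resid[map$nucleic_res]
  map <- dplyr::arrange(map, .data$protein_res, .data$nucleic_res, .data$class)

  events <- cand[c("type", "protein_atom", "nucleic_atom", "protein_res",
                   "nucleic_res", "class", "occupancy", "kept")]
  events$protein_atom_name <- atoms$name[events$protein_atom]
  events$nucleic_atom_name <- atoms$name[events$nucleic_atom]
  structure(list(map = map, events = tibble::as_tibble(events),
                 presence = pres[kept, , drop = FALSE],
                 n_frames = nf, criteria = criteria,
                 persistence = persistence),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat("<contact_map> ", nrow(x$map), " residue-pair/class entries from ",
      sum(x$events$kept & x$events$occupancy > 0), " persistent events (",
      nrow(x$events), " candidates, ", x$n_frames, " frames, persistence > ",
      x$persistence, ")\n", sep = "")
  print(x$map)
  invisible(x)
}

#' Write a contact map as tidy CSV/JSON
#'
#' Writes `<prefix>_map.csv` (residue-pair strengths), `<prefix>_events.csv`
#' (atom-level occupancies) and `<prefix>_map.json`.
#'
#' @param cm A `contact_map`.
#' @param prefix Output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_contact_map <- function(cm, prefix) {
  p1 <- paste0(prefix, "_map.csv")
  p2 <- paste0(prefix, "_events.csv")
  p3 <- paste0(prefix, "_map.json")
  utils::write.csv(cm$map, p1, row.names = FALSE)
  utils::write.csv(cm$events, p2, row.names = FALSE)
  jsonlite::write_json(list(
    n_frames = cm$n_frames, persistence = cm$persistence,
    map = cm$map), p3, auto_unbox = TRUE, digits = NA)
  invisible(c(p1, p2, p3))
}
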