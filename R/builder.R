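# Synthetic-data generators: ideal duplex builder (exact inverse of the
# helical-geometry measurement), probe complexes with scripted contacts, and
# Gaussian-fluctuation trajectories with known covariance.

#' Form presets for the duplex builder
#'
#' Package conventions (not measurements): B-form DNA twist 36.0 deg, rise
#' 3.38 A; A-form RNA twist 32.7 deg, rise 2.81 A, roll 8.0 deg,
#' x-displacement -4.0 A.
#' @export
DUPLEX_PRESETS <- list(
  B_DNA = list(shift = 0, slide = 0, rise = 3.38, tilt = 0, roll = 0,
               twist = 36.0, x_displacement = 0, propeller = 0,
               alphabet = c("A", "C", "G", "T"), sugar = "B"),
  A_RNA = list(shift = 0, slide = 0, rise = 2.81, tilt = 0, roll = 8.0,
               twist = 32.7, x_displacement = -4.0, propeller = 0,
               alphabet = c("A", "C", "G", "U"), sugar = "A")
)

#' Specification of an ideal duplex
#'
#' @param sequence One strand, 5'->3', as a string over `ACGT` (B_DNA) or
#'   `ACGU` (A_RNA).
#' @param form `"B_DNA"`, `"A_RNA"` or `"custom"`.
#' @param step_params Optional data frame with `length(sequence) - 1` rows
#'   and columns `shift`, `slide`, `rise`, `tilt`, `roll`, `twist`
#'   (A and deg); defaults to the form preset repeated.
#' @param pair_params Optional data frame with one row per pair and columns
#'   `propeller` (deg) and/or `x_displacement` (A).  A nonzero
#'   x-displacement requires uniform step parameters (the duplex is then
#'   built on an explicit helical axis).
#' @param include_hydrogens Add nucleobase hydrogens (default `FALSE`;
#'   sugar-phosphate hydrogens are never modelled).
#' @param sugar Sugar pucker template, `"B"` (C2'-endo) or `"A"` (C3'-endo);
#'   defaults to the form's convention.
#' @return A `duplex_spec` list.
#' @export
duplex_spec <- function(sequence, form = c("B_DNA", "A_RNA", "custom"),
                        step_params = NULL, pair_params = NULL,
                        include_hydrogens = FALSE, sugar = NULL) {
  form <- match.arg(form)
  bases <- strsplit(toupper(sequence), "")[[1]]
  if (length(bases) < 2) stop("sequence must have at least 2 bases")
  alphabet <- if (form == "custom") {
    if ("U" %in% bases) c("A", "C", "G", "U") else c("A", "C", "G", "T")
  } else DUPLEX_PRESETS[[form]]$alphabet
  bad <- setdiff(bases, alphabet)
  if (length(bad) > 0) {
    stop("base symbol(s) ", paste(unique(bad), collapse = ", "),
         " not in the ", form, " alphabet {",
         paste(alphabet, collapse = ""), "}")
  }
  preset <- DUPLEX_PRESETS[[if (form == "custom") "B_DNA" else form]]
  n <- length(bases)
  if (is.null(step_params)) {
    step_params <- tibble::tibble(
      shift = rep(preset$shift, n - 1), slide = preset$slide,
      rise = preset$rise, tilt = preset$tilt, roll = preset$roll,
      twist = preset$twist)
  } else {
    step_params <- tibble::as_tibble(step_params)
    need <- c("shift", "slide", "rise", "tilt", "roll", "twist")
    if (!all(need %in% names(step_params)) || nrow(step_params) != n - 1) {
      stop("step_params needs columns ", paste(need, collapse = ", "),
           " and ", n - 1, " rows")
    }
  }
  if (is.null(pair_params)) {
    pair_params <- tibble::tibble(
      propeller = rep(preset$propeller, n),
      x_displacement = rep(preset$x_displacement, n))
  } else {
    pair_params <- tibble::as_tibble(pair_params)
    if (is.null(pair_params$propeller)) pair_params$propeller <- 0
    if (is.null(pair_params$x_displacement)) pair_params$x_displacement <- 0
    if (nrow(pair_params) != n) stop("pair_params needs one row per pair")
  }
  rna <- "U" %in% alphabet
  structure(list(
    bases = bases, form = form, rna = rna,
    step_params = step_params, pair_params = pair_params,
    include_hydrogens = include_hydrogens,
    sugar = if (is.null(sugar)) (if (rna) "A" else "B") else sugar),
    class = "duplex_spec")
}

# chain of pair frames from step parameters (identity frame at the origin)
pair_frames_from_steps <- function(step_params) {
  n <- nrow(step_params) + 1
  frames <- vector("list", n)
  frames[[1]] <- new_frame(diag(3), c(0, 0, 0))
  for (s in seq_len(n - 1)) {
    frames[[s + 1]] <- frame_step_apply(
      frames[[s]], step_params$shift[s], step_params$slide[s],
      step_params$rise[s], step_params$tilt[s], step_params$roll[s],
      step_params$twist[s])$frame
  }
  frames
}

# uniform helix construction honouring a prescribed x-displacement: pair i
# has frame Rz(i*Omega) %*% B and origin Rz(i*Omega) %*% (dx, 0, 0) + i*h*z;
# (Omega, eta, h) are solved so the measured twist/roll/rise match the
# requested step parameters exactly (tilt, shift, slide become derived).
pair_frames_helical <- function(n, twist, roll, rise, x_disp) {
  target <- function(par) {
    B <- rot_x(par[2])
    f1 <- new_frame(B, c(x_disp, 0, 0))
    f2 <- new_frame(rot_z(par[1]) %*% B,
                    as.numeric(rot_z(par[1]) %*% c(x_disp, 0, 0)) +
                      c(0, 0, par[3]))
    dec <- mid_frame_decompose(f1, f2)
    c(dec$twist - twist, dec$roll - roll, dec$rise - rise)
  }
  sol <- stats::optim(c(twist, -roll, rise), function(p) sum(target(p)^2),
                      method = "BFGS",
                      control = list(reltol = 1e-15, maxit = 500))
  if (sol$value > 1e-10) {
    stop("helical construction did not converge for twist=", twist,
         ", roll=", roll, ", x_displacement=", x_disp)
  }
  par <- sol$par
  B <- rot_x(par[2])
  lapply(seq_len(n) - 1, function(i) {
    Rz <- rot_z(par[1] * i)
    new_frame(Rz %*% B,
              as.numeric(Rz %*% c(x_disp, 0, 0)) + c(0, 0, par[3] * i))
  })
}

#' Build an ideal duplex with prescribed helical parameters
#'
#' Generates full heavy-atom coordinates for a Watson-Crick duplex by
#' composing base-pair frames through the exact mid-step-frame transform that
#' [pair_and_step_parameters()] inverts, then placing standard-geometry
#' nucleotides in each base frame.  Phosphates are present on all
#' non-5'-terminal residues.  A bundled parameter table
#' ([synthetic_parameter_table()]) makes the result usable by the energy
#' module directly.
#'
#' @param spec A [duplex_spec].
#' @return List with `system` ([mol_system], classified), `coords`
#'   (`n_atoms x 3`), `pairing` (tibble `strand1`/`strand2` of residue
#'   indices, 5'->3' of strand 1), `step_params` (the table used),
#'   `param_table`.
#' @export
build_ideal_duplex <- function(spec) {
  stopifnot(inherits(spec, "duplex_spec"))
  n <- length(spec$bases)
  sp <- spec$step_params
  dx <- spec$pair_params$x_displacement
  uniform <- function(v) all(abs(v - v[1]) < 1e-12)
  if (any(dx != 0)) {
    ok <- uniform(dx) && all(vapply(sp, uniform, logical(1))) &&
      all(abs(c(sp$shift[1], sp$slide[1], sp$tilt[1])) < 1e-12)
    if (!ok) {
      stop("nonzero x_displacement requires uniform twist/roll/rise and ",
           "zero shift/slide/tilt (helical-axis construction)")
    }
    frames <- pair_frames_helical(n, sp$twist[1], sp$roll[1], sp$rise[1],
                                  dx[1])
  } else {
    frames <- pair_frames_from_steps(sp)
  }

  comp <- if (spec$rna) WC_COMPLEMENT_RNA else WC_COMPLEMENT
  resname_of <- function(code) if (spec$rna) code else paste0("D", code)
  rows <- list(); coords <- list()
  add_residue <- function(code, axes, origin, resid, chain, drop_phosphate) {
    tpl <- nucleotide_template(code, spec$sugar, o2prime = spec$rna,
                               hydrogens = spec$include_hydrogens)
    if (drop_phosphate) tpl <- tpl[!tpl$name %in% c("P", "OP1", "OP2"), ]
    xyz <- as.matrix(tpl[, c("x", "y", "z")]) %*% t(axes)
    xyz <- sweep(xyz, 2, origin, "+")
    rows[[length(rows) + 1]] <<- tibble::tibble(
      name = tpl$name, element = tpl$element,
      resname = resname_of(code), resid = resid, chain = chain)
    coords[[length(coords) + 1]] <<- xyz
  }
  flip <- diag(c(1, -1, -1))
  for (lev in seq_len(n)) {
    f <- frames[[lev]]
    prop <- spec$pair_params$propeller[lev]
    axes_i <- f$axes %*% rot_y(prop / 2)
    add_residue(spec$bases[lev], axes_i, f$origin, lev, "B", lev == 1)
  }
  for (k in seq_len(n)) {
    lev <- n + 1 - k   # strand II runs antiparallel: its 5' end pairs level n
    f <- frames[[lev]]
    prop <- spec$pair_params$propeller[lev]
    axes_j <- f$axes %*% rot_y(-prop / 2) %*% flip
    add_residue(unname(comp[spec$bases[lev]]), axes_j, f$origin, k, "C",
                k == 1)
  }
  atoms <- dplyr::bind_rows(rows)
  xyz <- do.call(rbind, coords)
  system <- mol_system(atoms)
  system <- classify_atoms(system)
  system$bonds <- infer_bonds(system, xyz)
  pairing <- tibble::tibble(
    strand1 = seq_len(n),
    strand2 = n + (n:1))
  list(system = system, coords = xyz, pairing = pairing,
       step_params = sp, param_table = synthetic_parameter_table(system))
}

# ---- probe complexes --------------------------------------------------------

# Minimal amino-acid probe templates in a local frame: the "contact atom"
# sits at the origin and the rest of the residue extends along +x (which the
# placement routine points away from the duplex).  Real residue names are
# used so classification, parameter loading and the detectors run unmodified.
PROBE_TEMPLATES <- list(
  # serine side-chain hydroxyl donor (OG-HG); CB is excluded from apolar
  # carbons because it bonds OG
  hbond = list(
    resname = "SER", contact = "OG",
    atoms = tibble::tibble(
      name = c("OG", "HG", "CB", "CA", "N", "C", "O"),
      element = c("O", "H", "C", "C", "N", "C", "O"),
      x = c(0, -0.96, 1.30, 2.20, 3.10, 2.95, 3.35),
      y = c(0, 0, 0.60, -0.45, 0.35, -1.55, -2.65),
      z = c(0, 0, 0, 0, 0.45, -0.55, -0.35))),
  # lysine ammonium nitrogen; hydrogens point sideways/back so the probe
  # cannot satisfy the hydrogen-bond angle criterion
  salt_bridge = list(
    resname = "LYS", contact = "NZ",
    atoms = tibble::tibble(
      name = c("NZ", "HZ1", "HZ2", "HZ3", "CE", "CD", "CG", "CB", "CA",
               "N", "C", "O"),
      element = c("N", "H", "H", "H", "C", "C", "C", "C", "C", "N", "C", "O"),
      x = c(0, 0.35, 0.35, 0.35, 1.45, 2.30, 3.75, 4.60, 6.05, 6.80, 6.55, 6.20),
      y = c(0, 0.95, -0.80, -0.15, 0.25, -0.95, -0.70, 0.30, 0.20, 1.35, -1.10, -2.20),
      z = c(0, 0, 0.55, -0.95, -0.30, -0.60, -0.45, 0.35, 0.30, 0.75, -0.75, -0.40))),
  # valine methyl carbon; CG1 and CG2/CB are apolar
  apolar = list(
    resname = "VAL", contact = "CG1",
    atoms = tibble::tibble(
      name = c("CG1", "CB", "CG2", "CA", "N", "C", "O"),
      element = c("C", "C", "C", "C", "N", "C", "O"),
      x = c(0, 1.52, 2.05, 2.30, 3.20, 3.10, 3.55),
      y = c(0, 0.25, 1.55, -0.85, -0.15, -2.05, -3.10),
      z = c(0, 0, 0.30, -0.75, -1.35, -0.35, -0.80))),
  # threonine-like dual probe: OG1-HG1 donates a hydrogen bond to the primary
  # target while the CG2 methyl (apolar: bonded to CB only) reaches a nearby
  # carbon of the same residue -- one residue pair, two simultaneous contacts
  hbond_apolar = list(
    resname = "THR", contact = "OG1",
    atoms = tibble::tibble(
      name = c("OG1", "HG1", "CB", "CG2", "CA", "N", "C", "O"),
      element = c("O", "H", "C", "C", "C", "N", "C", "O"),
      x = c(0, -0.96, 0.80, -0.10, 2.25, 2.95, 2.85, 3.15),
      y = c(0, 0, 1.15, 2.40, 1.30, 2.50, 0.15, -0.95),
      z = c(0, 0, 0, 0.50, 0.25, 0.45, -0.60, -0.25)))
)

# on-geometry distances per contact kind (margins inside the default
# criteria) and the off-frame extra displacement along the outward direction
PROBE_GEOMETRY <- list(
  hbond = list(d_on = 2.85, d_off_extra = 2.5),
  salt_bridge = list(d_on = 3.50, d_off_extra = 2.5),
  apolar = list(d_on = 4.00, d_off_extra = 2.5),
  hbond_apolar = list(d_on = 2.85, d_off_extra = 2.5)
)

#' Scripted contact schedule entry
#'
#' @param kind Contact type: `"hbond"`, `"salt_bridge"`, `"apolar"` or
#'   `"hbond_apolar"` (a dual probe forming both contact types to the same
#'   residue simultaneously).
#' @param target_residue Duplex residue index (`res_index`).
#' @param target_atom Atom name on that residue (acceptor oxygen/nitrogen for
#'   hbond, phosphate oxygen for salt bridges, apolar carbon for apolar).
#' @param pattern Logical presence vector, one element per frame.
#' @param secondary_atom For `"hbond_apolar"`: the apolar carbon on the same
#'   residue that the probe methyl must reach (e.g. thymine `C7`).
#' @return A one-row tibble usable in a schedule.
#' @export
contact_schedule_entry <- function(kind, target_residue, target_atom,
                                   pattern, secondary_atom = NA) {
  kind <- match.arg(kind, c("hbond", "salt_bridge", "apolar", "hbond_apolar"))
  if (kind == "hbond_apolar" && is.na(secondary_atom)) {
    stop("hbond_apolar entries need a secondary_atom")
  }
  tibble::tibble(kind = kind, target_residue = as.integer(target_residue),
                 target_atom = normalize_atom_name(target_atom),
                 secondary_atom = if (is.na(secondary_atom)) NA_character_
                                  else normalize_atom_name(secondary_atom),
                 pattern = list(as.logical(pattern)))
}

#' Build a probe complex with scripted contacts
#'
#' Places one minimal amino-acid probe residue per schedule entry so that in
#' "on" frames the scheduled contact satisfies its geometric criterion with
#' margin (e.g. donor-acceptor 2.85 A at 180 deg) and in "off" frames the
#' probe is displaced outward by 2.5 A, violating the criterion by at least
#' 2 A.  Probes extend radially outward along the bond direction of the
#' target atom, so no unscheduled interface contacts arise (verified by a
#' clash check).  The duplex itself is static across frames.
#'
#' @param duplex Result of [build_ideal_duplex()].
#' @param schedule Tibble of [contact_schedule_entry()] rows; all patterns
#'   must share one length (the frame count).
#' @param clash_tol Minimum allowed probe-duplex heavy-atom distance beyond
#'   the scheduled contact (default 2.5 A).
#' @return List with `system` (classified, parameterized [mol_system]),
#'   `traj` ([traj_ensemble]), `param_table`, `schedule`.
#' @export
make_probe_complex <- function(duplex, schedule, clash_tol = 2.5) {
  if (nrow(schedule) == 0) stop("schedule must have at least one entry")
  n_f <- length(schedule$pattern[[1]])
  if (any(vapply(schedule$pattern, length, 1L) != n_f)) {
    stop("all schedule patterns must have the same length")
  }
  datoms <- duplex$system$atoms
  dn <- nrow(datoms)
  placements <- vector("list", nrow(schedule))
  rows <- list(atoms = list())
  next_resid <- 1L
  for (k in seq_len(nrow(schedule))) {
    kind <- schedule$kind[k]
    tpl <- PROBE_TEMPLATES[[kind]]
    geo <- PROBE_GEOMETRY[[kind]]
    t_idx <- which(datoms$res_index == schedule$target_residue[k] &
                   datoms$name == schedule$target_atom[k])
    if (length(t_idx) == 0) {
      stop("target atom ", schedule$target_atom[k], " not found on residue ",
           schedule$target_residue[k])
    }
    target <- duplex$coords[t_idx, ]
    nb <- bonded_neighbors(duplex$system, t_idx)
    if (length(nb) == 0) stop("target atom has no bonded neighbour")
    u <- unit3(target - duplex$coords[nb[1], ])
    # Contact atom sits along the target's bond direction, which keeps it
    # clear of the target's own neighbours.  Salt-bridge probes additionally
    # tilt their tail radially out of the helix so the side chain cannot lie
    # across a groove (hydrogen-bond probes must keep the donor H on the
    # bond axis, and their base-edge targets already point outward).
    u_orient <- u
    if (kind == "salt_bridge") {
      cen <- colMeans(duplex$coords)
      axis <- eigen(stats::cov(duplex$coords), symmetric = TRUE)$vectors[, 1]
      w <- target - cen
      w <- w - sum(w * axis) * axis
      if (sqrt(sum(w^2)) > 1) u_orient <- unit3(0.5 * u + unit3(w))
    }
    # local frame: x along +u (outward); +y toward the secondary target if
    # one is given, otherwise any orthonormal completion
    sec <- schedule$secondary_atom
    if (!is.null(sec) && !is.na(sec[k])) {
      s_idx <- which(datoms$res_index == schedule$target_residue[k] &
                     datoms$name == sec[k])
      if (length(s_idx) == 0) {
        stop("secondary atom ", sec[k], " not found on residue ",
             schedule$target_residue[k])
      }
      ws <- duplex$coords[s_idx, ] - target
      ws <- ws - sum(ws * u) * u
      e2 <- unit3(ws)
      e3 <- cross3(u, e2)
      R <- cbind(u, e2, e3)
    } else {
      ref <- if (abs(u_orient[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      e2 <- unit3(cross3(u_orient, ref))
      e3 <- cross3(u_orient, e2)
      R <- cbind(u_orient, e2, e3)
    }
    base_on <- target + geo$d_on * u
    tpl_xyz <- as.matrix(tpl$atoms[, c("x", "y", "z")]) %*% t(R)
    on_xyz <- sweep(tpl_xyz, 2, base_on, "+")
    off_xyz <- sweep(on_xyz, 2, geo$d_off_extra * u, "+")
    # clash check on the on-position (scheduled contact atom exempt)
    heavy_probe <- which(tpl$atoms$element != "H")
    heavy_dup <- which(datoms$element != "H")
    dmin <- min(vapply(heavy_probe, function(i) {
      d <- sqrt(rowSums(sweep(duplex$coords[heavy_dup, , drop = FALSE], 2,
                              on_xyz[i, ])^2))
      if (i == 1) sort(d)[2] else min(d)   # nearest beyond the target itself
    }, numeric(1)))
    if (dmin < clash_tol) {
      stop("unrealizable placement for schedule entry ", k,
           ": probe-duplex distance ", round(dmin, 2), " A < ", clash_tol)
    }
    placements[[k]] <- list(on = on_xyz, off = off_xyz,
                            pattern = schedule$pattern[[k]])
    rows$atoms[[k]] <- tibble::tibble(
      name = tpl$atoms$name, element = tpl$atoms$element,
      resname = tpl$resname, resid = next_resid, chain = "P")
    next_resid <- next_resid + 1L
  }
  atoms <- dplyr::bind_rows(c(list(datoms[c("name", "element", "resname",
                                            "resid", "chain")]), rows$atoms))
  system <- mol_system(atoms)
  system <- classify_atoms(system)
  ref_coords <- rbind(duplex$coords,
                      do.call(rbind, lapply(placements, `[[`, "on")))
  system$bonds <- infer_bonds(system, ref_coords)
  xyz <- matrix(NA_real_, nrow = n_f, ncol = 3 * nrow(atoms))
  dup_flat <- coords_to_xyz(duplex$coords)
  for (f in seq_len(n_f)) {
    parts <- lapply(placements, function(p) {
      if (p$pattern[f]) p$on else p$off
    })
    xyz[f, ] <- c(dup_flat, coords_to_xyz(do.call(rbind, parts)))
  }
  traj <- traj_ensemble(system, xyz)
  param_table <- synthetic_parameter_table(system)
  system <- load_parameters(system, param_table)
  traj$system <- system
  list(system = system, traj = traj, param_table = param_table,
       schedule = schedule)
}

# ---- Gaussian-fluctuation trajectories --------------------------------------

run_seeded <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = .GlobalEnv)) {
      get(".Random.seed", envir = .GlobalEnv)
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = .GlobalEnv)) {
          rm(".Random.seed", envir = .GlobalEnv)
        }
      } else assign(".Random.seed", old, envir = .GlobalEnv)
    })
    set.seed(seed)
  }
  force(code())
}

#' Sample a Gaussian-fluctuation trajectory with known covariance
#'
#' Frames are `reference + eps_f`, with `eps_f` zero-mean multivariate
#' Gaussian draws from the given 3N x 3N covariance (via its symmetric
#' eigen-factorization).  Optional rigid-body jitter applies a random
#' rotation/translation per frame, to exercise superposition-based analyses.
#' Output is reproducible: a fixed seed gives identical trajectories.
#'
#' @param system A [mol_system].
#' @param reference `n_atoms x 3` reference coordinates.
#' @param covariance Either a full 3N x 3N PSD matrix, a length-3N (or
#'   scalar) diagonal, or a list `list(spike = v, spike_var = s2, iso = v0)`
#'   for a rank-one spike (unit vector `v`, variance `s2`) on isotropic
#'   noise `v0`.
#' @param n_frames Number of frames.
#' @param seed Integer seed.
#' @param rigid_jitter If `TRUE`, add random rigid-body motion per frame.
#' @return A [traj_ensemble]; the realised generating covariance matrix is
#'   attached as attribute `"covariance"`.
#' @export
gaussian_trajectory <- function(system, reference, covariance, n_frames,
                                seed = 1, rigid_jitter = FALSE) {
  n3 <- 3 * n_atoms(system)
  C <- if (is.list(covariance)) {
    v <- unit3_n(covariance$spike)
    if (length(v) != n3) stop("spike vector must have length 3N")
    covariance$spike_var * outer(v, v) + covariance$iso * diag(n3)
  } else if (is.matrix(covariance)) {
    if (nrow(covariance) != n3) stop("covariance must be 3N x 3N")
    covariance
  } else {
    diag(rep(covariance, length.out = n3), nrow = n3)
  }
  C <- (C + t(C)) / 2
  eg <- eigen(C, symmetric = TRUE)
  if (any(eg$values < -1e-8 * max(abs(eg$values), 1))) {
    stop("covariance is not positive semidefinite")
  }
  A <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
  ref_flat <- coords_to_xyz(reference)
  xyz <- run_seeded(seed, function() {
    Z <- matrix(stats::rnorm(n_frames * n3), nrow = n_frames)
    X <- Z %*% A
    X <- sweep(X, 2, ref_flat, "+")
    if (rigid_jitter) {
      for (f in seq_len(n_frames)) {
        ax <- stats::rnorm(3)
        R <- rot_axis(ax, stats::runif(1, -180, 180))
        tr <- stats::rnorm(3, sd = 5)
        m <- xyz_to_coords(X[f, ]) %*% t(R)
        X[f, ] <- coords_to_xyz(sweep(m, 2, tr, "+"))
      }
    }
    X
  })
  out <- traj_ensemble(system, xyz)
  attr(out, "covariance") <- C
  out
}

unit3_n <- function(v) v / sqrt(sum(v^2))

#' Random collective mode orthogonal to rigid-body motion
#'
#' Draws a random unit 3N-vector and projects out the six rigid-body degrees
#' of freedom (translations and infinitesimal rotations about the reference
#' centroid).  Spiked-covariance trajectories built along such a mode
#' survive superposition, so PCA ground-truth tests can run under the same
#' superposition protocol as production analyses.
#'
#' @param reference `n_atoms x 3` reference coordinates.
#' @param seed Integer seed for the random draw.
#' @return Unit numeric vector of length `3 * n_atoms`.
#' @export
rigid_orthogonal_mode <- function(reference, seed = 1) {
  n <- nrow(reference)
  cen <- sweep(reference, 2, colMeans(reference))
  basis <- matrix(0, 3 * n, 6)
  for (k in 1:3) basis[seq(k, 3 * n, by = 3), k] <- 1
  for (k in 1:3) {
    ax <- diag(3)[, k]
    disp <- t(apply(cen, 1, function(p) cross3(ax, p)))
    basis[, 3 + k] <- as.numeric(t(disp))
  }
  Q <- qr.Q(qr(basis))
  v <- run_seeded(seed, function() stats::rnorm(3 * n))
  v <- v - Q %*% (t(Q) %*% v)
  unit3_n(as.numeric(v))
}

#' Minimal single-atom-per-particle system for Gaussian toys
#'
#' A convenience topology of `n` phosphorus-like particles (one residue
#' each), for entropy/PCA ground-truth trajectories.
#'
#' @param n Number of particles.
#' @param mass Mass per particle, amu (default 30.973762, phosphorus).
#' @return A [mol_system] with masses set.
#' @export
toy_particle_system <- function(n, mass = 30.973762) {
  sys <- mol_system(tibble::tibble(
    name = rep("P", n), element = rep("P", n),
    resname = rep("UNK", n), resid = seq_len(n), chain = "X"))
  sys$atoms$mass <- mass
  sys
}
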