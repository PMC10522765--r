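# Base-pair and base-pair-step geometry via the mid-step-frame (CEHS-style)
# construction, plus groove geometry and backbone torsions.  The builder in
# builder.R composes pair frames through the exact transform this module
# inverts, so build -> measure is an identity for the step parameters.

ANGULAR_PARAMETERS <- c("tilt", "roll", "twist", "propeller", "buckle",
                        "opening", "alpha", "beta", "gamma", "delta",
                        "epsilon", "zeta", "chi")

#' Reference frame of one base from its atoms
#'
#' Least-squares fits the standard planar base geometry onto the observed
#' base atoms (Kabsch, proper rotation) and returns the transformed standard
#' frame: origin plus orthonormal right-handed axes with x toward the major
#' groove, y along the C1'-C1' sense and z the stacking normal.
#'
#' @param coords Named-atom coordinates: `n x 3` matrix.
#' @param names Atom names matching `coords` rows.
#' @param base_type One of `"A"`, `"G"`, `"C"`, `"T"`, `"U"`.
#' @return List with `origin` (length 3), `axes` (3x3, columns x, y, z),
#'   `rmsd` of the fit (A).
#' @export
base_reference_frame <- function(coords, names, base_type) {
  bt <- BASE_TEMPLATES[[base_type]]
  if (is.null(bt)) stop("unknown base type: ", base_type)
  names <- normalize_atom_name(names)
  use <- bt$ring
  idx <- match(use, names)
  if (anyNA(idx)) {
    stop("missing ring atom(s) for base frame: ",
         paste(use[is.na(idx)], collapse = ", "))
  }
  tpl <- bt$coords[match(use, bt$atoms), , drop = FALSE]
  obs <- coords[idx, , drop = FALSE]
  # fit template -> observed: obs ~ tpl %*% t(R) + t
  fit <- superpose(tpl, obs, seq_len(nrow(tpl)))
  list(origin = as.numeric(fit$translation),
       axes = fit$rotation, rmsd = fit$rmsd)
}

new_frame <- function(axes, origin) list(axes = axes, origin = origin)

flip_frame <- function(f) {
  new_frame(f$axes %*% diag(c(1, -1, -1)), f$origin)
}

# CEHS mid-frame decomposition between two frames: rotation split into a
# hinge (roll/tilt) bend of magnitude Gamma and a twist about the mean
# z-axis; translations expressed in the mid-frame.
mid_frame_decompose <- function(f1, f2) {
  R1 <- f1$axes; R2 <- f2$axes
  z1 <- R1[, 3]; z2 <- R2[, 3]
  cg <- min(max(sum(z1 * z2), -1), 1)
  cr <- cross3(z1, z2)
  gamma <- rad2deg(atan2(sqrt(sum(cr^2)), cg))
  if (sqrt(sum(cr^2)) > 1e-12) {
    hinge <- unit3(cr)
    R1p <- rot_axis(hinge, gamma / 2) %*% R1
    R2p <- rot_axis(hinge, -gamma / 2) %*% R2
  } else {
    hinge <- R1[, 2]
    R1p <- R1; R2p <- R2
  }
  zm <- unit3(R1p[, 3] + R2p[, 3])
  twist <- signed_angle(R1p[, 1], R2p[, 1], zm)
  xm <- unit3(R1p[, 1] + R2p[, 1])
  ym <- unit3(cross3(zm, xm))
  M <- cbind(unit3(cross3(ym, zm)), ym, zm)
  phi <- if (gamma > 1e-9) signed_angle(hinge, ym, zm) else 0
  om <- (f1$origin + f2$origin) / 2
  tr <- as.numeric(t(M) %*% (f2$origin - f1$origin))
  list(shift = tr[1], slide = tr[2], rise = tr[3],
       tilt = gamma * sin(deg2rad(phi)), roll = gamma * cos(deg2rad(phi)),
       twist = twist, mid = new_frame(M, om))
}

# exact inverse of mid_frame_decompose: next frame from step parameters
frame_step_apply <- function(f1, shift, slide, rise, tilt, roll, twist) {
  gamma <- sqrt(roll^2 + tilt^2)
  phi <- rad2deg(atan2(tilt, roll))
  h_loc <- c(sin(deg2rad(phi)), cos(deg2rad(phi)), 0)
  A1 <- rot_axis3_safe(h_loc, -gamma / 2) %*% rot_z(-twist / 2)
  A2 <- rot_axis3_safe(h_loc, gamma / 2) %*% rot_z(twist / 2)
  M <- f1$axes %*% t(A1)
  R2 <- M %*% A2
  o2 <- f1$origin + as.numeric(M %*% c(shift, slide, rise))
  list(frame = new_frame(R2, o2), mid = new_frame(M, (f1$origin + o2) / 2))
}

rot_axis3_safe <- function(axis, angle_deg) {
  if (abs(angle_deg) < 1e-12) return(diag(3))
  rot_axis(axis, angle_deg)
}

# base frames of a residue pair -> pair frame and intra-pair parameters
pair_frame_from_bases <- function(frame_i, frame_j) {
  dec <- mid_frame_decompose(flip_frame(frame_j), frame_i)
  list(frame = dec$mid,
       propeller = dec$roll, buckle = dec$tilt, opening = dec$twist)
}

base_frames_of_pairs <- function(system, coords, pairing) {
  a <- system$atoms
  get_frame <- function(res_index) {
    sel <- which(a$res_index == res_index)
    code <- base_code_from_resname(a$resname[sel[1]])
    if (is.na(code)) stop("residue ", res_index, " is not a standard base")
    base_reference_frame(coords[sel, , drop = FALSE], a$name[sel], code)
  }
  lapply(seq_len(nrow(pairing)), function(k) {
    fi <- get_frame(pairing$strand1[k])
    fj <- get_frame(pairing$strand2[k])
    pf <- pair_frame_from_bases(new_frame(fi$axes, fi$origin),
                                new_frame(fj$axes, fj$origin))
    c(pf, list(base_i = fi, base_j = fj))
  })
}

# Moore-Penrose pseudo-inverse of a small matrix via SVD.
pinv3 <- function(A, tol = 1e-8) {
  sv <- svd(A)
  d <- ifelse(sv$d > tol * max(sv$d), 1 / sv$d, 0)
  sv$v %*% (d * t(sv$u))
}

# x-displacement of both flanking pairs w.r.t. the local helical (screw)
# axis of one step; NA when the step rotation is (near) zero.
step_xdisplacement <- function(pf1, pf2) {
  Q <- pf2$axes %*% t(pf1$axes)
  ang <- acos(min(max((sum(diag(Q)) - 1) / 2, -1), 1))
  if (ang < 1e-3) return(c(NA_real_, NA_real_))
  # rotation axis of Q
  u <- c(Q[3, 2] - Q[2, 3], Q[1, 3] - Q[3, 1], Q[2, 1] - Q[1, 2])
  if (sqrt(sum(u^2)) < 1e-9) {
    ev <- eigen(Q)
    u <- Re(ev$vectors[, which.min(abs(Re(ev$values) - 1))])
  }
  u <- unit3(u)
  d <- pf2$origin - as.numeric(Q %*% pf1$origin)
  rhs <- d - sum(d * u) * u
  p <- as.numeric(pinv3(diag(3) - Q) %*% rhs)
  vapply(list(pf1, pf2), function(pf) {
    aa <- pf$origin - p
    aperp <- aa - sum(aa * u) * u
    sum(aperp * pf$axes[, 1])
  }, numeric(1))
}

#' Base-pair and base-pair-step parameters of one duplex frame
#'
#' Computes per-pair parameters (propeller, buckle, opening, x-displacement)
#' and per-step parameters (shift, slide, rise in A; tilt, roll, twist in
#' deg) from fitted base reference frames.  Step rotations are decomposed
#' about the mid-step frame; translations are expressed in the mid-step
#' frame; x-displacement comes from the local helical (screw) axis of the
#' flanking steps.
#'
#' @param system A [mol_system].
#' @param coords One frame, `n_atoms x 3`.
#' @param pairing Pairing map: data frame with columns `strand1`, `strand2`
#'   (residue indices, `res_index`), consecutive duplex levels in 5'->3'
#'   order of strand 1.
#' @return List with `steps` (tibble: `step`, `shift`, `slide`, `rise`,
#'   `tilt`, `roll`, `twist`) and `pairs` (tibble: `level`, `propeller`,
#'   `buckle`, `opening`, `x_displacement`).
#' @export
pair_and_step_parameters <- function(system, coords, pairing) {
  pairing <- as.data.frame(pairing)
  if (nrow(pairing) < 2) stop("need at least two consecutive pairs")
  bf <- base_frames_of_pairs(system, coords, pairing)
  pair_frames <- lapply(bf, `[[`, "frame")
  n <- length(pair_frames)
  steps <- vector("list", n - 1)
  xd <- matrix(NA_real_, nrow = n, ncol = 2)  # per pair, from left/right step
  for (s in seq_len(n - 1)) {
    dec <- mid_frame_decompose(pair_frames[[s]], pair_frames[[s + 1]])
    steps[[s]] <- tibble::tibble(
      step = s, shift = dec$shift, slide = dec$slide, rise = dec$rise,
      tilt = dec$tilt, roll = dec$roll, twist = dec$twist)
    x2 <- step_xdisplacement(pair_frames[[s]], pair_frames[[s + 1]])
    xd[s, 2] <- x2[1]
    xd[s + 1, 1] <- x2[2]
  }
  pairs <- tibble::tibble(
    level = seq_len(n),
    propeller = vapply(bf, `[[`, 1, "propeller"),
    buckle = vapply(bf, `[[`, 1, "buckle"),
    opening = vapply(bf, `[[`, 1, "opening"),
    x_displacement = rowMeans(xd, na.rm = TRUE))
  pairs$x_displacement[is.nan(pairs$x_displacement)] <- NA_real_
  list(steps = dplyr::bind_rows(steps), pairs = pairs)
}

#' Groove widths and depths of one duplex frame
#'
#' Width: minimal cross-strand P-P distance within a groove-defining window
#' of sequence offsets, minus a 5.8 A phosphate van der Waals correction,
#' floored at 0.  Level indexing follows the 5' strand (strand 1 of the
#' pairing map).  For level i, phosphate pairs P1(i + a) vs P2(level i + b)
#' are searched with offsets `(a - b)` spanning the minor groove window on
#' one side and the major groove window on the other.  Depth: distance from
#' the midpoint of the width-defining P-P pair to the level's base-pair
#' origin, projected on the pair x-axis (major groove on +x).
#'
#' @param system A [mol_system].
#' @param coords One frame, `n_atoms x 3`.
#' @param pairing Pairing map (see [pair_and_step_parameters()]).
#' @param vdw_correction Phosphate vdW correction subtracted from raw P-P
#'   distances (default 5.8 A).
#' @return Tibble: `level`, `groove`, `width`, `depth` (A); levels whose
#'   window falls off the strand are skipped.
#' @export
groove_geometry <- function(system, coords, pairing, vdw_correction = 5.8) {
  pairing <- as.data.frame(pairing)
  n <- nrow(pairing)
  a <- system$atoms
  p_of <- function(res_index) {
    i <- which(a$res_index == res_index & a$name == "P")
    if (length(i) == 0) NA_integer_ else i[1]
  }
  p1 <- vapply(pairing$strand1, p_of, integer(1))
  p2 <- vapply(pairing$strand2, p_of, integer(1))
  if (all(is.na(p1)) || all(is.na(p2))) {
    stop("phosphates missing on one or both strands")
  }
  bf <- base_frames_of_pairs(system, coords, pairing)
  windows <- list(minor = GROOVE_WINDOWS$minor, major = GROOVE_WINDOWS$major)
  out <- list()
  for (lev in seq_len(n)) {
    for (g in names(windows)) {
      w <- windows[[g]]
      best <- Inf; best_mid <- NULL
      for (k in seq_len(nrow(w))) {
        i1 <- lev + w$a[k]; i2 <- lev + w$b[k]
        if (i1 < 1 || i1 > n || i2 < 1 || i2 > n) next
        if (is.na(p1[i1]) || is.na(p2[i2])) next
        d <- sqrt(sum((coords[p1[i1], ] - coords[p2[i2], ])^2))
        if (d < best) {
          best <- d
          best_mid <- (coords[p1[i1], ] + coords[p2[i2], ]) / 2
        }
      }
      if (!is.finite(best)) next
      f <- bf[[lev]]$frame
      depth <- abs(sum((best_mid - f$origin) * f$axes[, 1]))
      out[[length(out) + 1]] <- tibble::tibble(
        level = lev, groove = g,
        width = max(best - vdw_correction, 0), depth = depth)
    }
  }
  dplyr::bind_rows(out)
}

# Cross-strand offset windows (in duplex levels, relative to the scored
# level) for the minimal P-P groove distances: for level i the candidate
# phosphate pairs are P1(i + a) vs P2(level i + b).  Fixed package
# convention, calibrated on ideal B-form builds: the strand-offset
# (a - b) ~ +3..+5 side spans the minor groove, the mirrored window the
# major groove.  Level indexing is relative to the 5' strand (strand 1).
GROOVE_WINDOWS <- list(
  minor = data.frame(a = c(1, 2, 2, 2, 3), b = c(-2, -1, -2, -3, -2)),
  major = data.frame(a = c(-1, -2, -2, -2, -3), b = c(2, 1, 2, 3, 2))
)

#' Backbone torsion angles of a trajectory
#'
#' Computes the standard nucleic-acid backbone torsions alpha, beta, gamma,
#' delta, epsilon, zeta and the glycosidic chi per nucleotide per frame.
#' Angles whose defining atoms are missing (chain termini lacking a
#' phosphate) are `NA`.
#'
#' @param traj A [traj_ensemble] (or a single frame via `coords`).
#' @param frames Frame indices to analyse (default all).
#' @return Tibble: `frame`, `res_index`, `resname`, `chain`, `angle`,
#'   `value` (deg).
#' @export
backbone_torsions <- function(traj, frames = NULL) {
  system <- traj$system
  a <- system$atoms
  res <- system$residues
  nuc_res <- res$res_index[res$polymer == "nucleic"]
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  atom_of <- function(res_index, name) {
    i <- which(a$res_index == res_index & a$name == name)
    if (length(i) == 0) NA_integer_ else i[1]
  }
  # torsion atom quadruples per residue (atom indices, NA-> undefined)
  defs <- list()
  for (ri in nuc_res) {
    chain <- res$chain[res$res_index == ri]
    prev <- ri - 1L
    nxt <- ri + 1L
    same_chain <- function(rj) {
      rj %in% res$res_index && res$chain[res$res_index == rj] == chain &&
        res$polymer[res$res_index == rj] == "nucleic"
    }
    o3_prev <- if (same_chain(prev)) atom_of(prev, "O3'") else NA_integer_
    p_next <- if (same_chain(nxt)) atom_of(nxt, "P") else NA_integer_
    o5_next <- if (same_chain(nxt)) atom_of(nxt, "O5'") else NA_integer_
    code <- base_code_from_resname(res$resname[res$res_index == ri])
    glyc <- if (!is.na(code) && code %in% c("A", "G")) c("N9", "C4") else c("N1", "C2")
    quad <- list(
      alpha = c(o3_prev, atom_of(ri, "P"), atom_of(ri, "O5'"), atom_of(ri, "C5'")),
      beta = c(atom_of(ri, "P"), atom_of(ri, "O5'"), atom_of(ri, "C5'"), atom_of(ri, "C4'")),
      gamma = c(atom_of(ri, "O5'"), atom_of(ri, "C5'"), atom_of(ri, "C4'"), atom_of(ri, "C3'")),
      delta = c(atom_of(ri, "C5'"), atom_of(ri, "C4'"), atom_of(ri, "C3'"), atom_of(ri, "O3'")),
      epsilon = c(atom_of(ri, "C4'"), atom_of(ri, "C3'"), atom_of(ri, "O3'"), p_next),
      zeta = c(atom_of(ri, "C3'"), atom_of(ri, "O3'"), p_next, o5_next),
      chi = c(atom_of(ri, "O4'"), atom_of(ri, "C1'"), atom_of(ri, glyc[1]),
              atom_of(ri, glyc[2])))
    defs[[as.character(ri)]] <- quad
  }
  rows <- list()
  for (f in frames) {
    coords <- frame_coords(traj, f)
    for (ri in nuc_res) {
      quad <- defs[[as.character(ri)]]
      for (ang in names(quad)) {
        q <- quad[[ang]]
        val <- if (anyNA(q)) NA_real_ else {
          dihedral_angle(coords[q[1], ], coords[q[2], ],
                         coords[q[3], ], coords[q[4], ])
        }
        rows[[length(rows) + 1]] <- tibble::tibble(
          frame = f, res_index = ri,
          resname = res$resname[res$res_index == ri],
          chain = res$chain[res$res_index == ri],
          angle = ang, value = val)
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Helical parameter series over a trajectory
#'
#' Runs [pair_and_step_parameters()] and [groove_geometry()] on each frame
#' and returns tidy long tibbles.
#'
#' @param traj A [traj_ensemble].
#' @param pairing Pairing map (see [pair_and_step_parameters()]).
#' @param frames Frame indices (default all).
#' @param grooves Also compute groove geometry (default `TRUE`).
#' @return List of tibbles `steps`, `pairs` and (optionally) `grooves`, each
#'   long with a `frame` column.
#' @export
helical_series <- function(traj, pairing, frames = NULL, grooves = TRUE) {
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  st <- list(); pr <- list(); gr <- list()
  for (f in frames) {
    coords <- frame_coords(traj, f)
    ps <- pair_and_step_parameters(traj$system, coords, pairing)
    st[[length(st) + 1]] <- dplyr::mutate(
      tidyr::pivot_longer(ps$steps, -"step", names_to = "parameter",
                          values_to = "value"), frame = f)
    pr[[length(pr) + 1]] <- dplyr::mutate(
      tidyr::pivot_longer(ps$pairs, -"level", names_to = "parameter",
                          values_to = "value"), frame = f)
    if (grooves) {
      gg <- groove_geometry(traj$system, coords, pairing)
      gr[[length(gr) + 1]] <- dplyr::mutate(
        tidyr::pivot_longer(gg, c("width", "depth"), names_to = "parameter",
                            values_to = "value"), frame = f)
    }
  }
  out <- list(steps = dplyr::bind_rows(st), pairs = dplyr::bind_rows(pr))
  if (grooves) out$grooves <- dplyr::bind_rows(gr)
  out
}

#' Summarise a helical parameter series
#'
#' Per (position, parameter) trajectory means and SDs -- circular statistics
#' for angular parameters -- plus fixed-bin histograms for distribution
#' plots.
#'
#' @param series Long tibble with columns `frame`, `parameter`, `value` and a
#'   position column (`step` or `level`).
#' @param position Name of the position column (default `"step"`).
#' @param n_bins Histogram bin count (default 36).
#' @return List with `summary` (position, parameter, mean, sd, n) and
#'   `histogram` (position, parameter, bin_mid, count).
#' @export
parameter_series_summary <- function(series, position = "step", n_bins = 36) {
  pos <- series[[position]]
  key <- paste(pos, series$parameter)
  groups <- unique(key)
  summ <- list(); hist_rows <- list()
  for (g in groups) {
    sel <- key == g
    vals <- series$value[sel]
    par <- series$parameter[sel][1]
    angular <- par %in% ANGULAR_PARAMETERS
    mu <- if (angular) circular_mean(vals) else mean(vals, na.rm = TRUE)
    sdv <- if (angular) circular_sd(vals) else stats::sd(vals)
    summ[[g]] <- tibble::tibble(
      position = pos[sel][1], parameter = par, mean = mu, sd = sdv,
      n = sum(!is.na(vals)))
    vv <- vals[!is.na(vals)]
    if (length(vv) > 0) {
      rng <- range(vv)
      if (diff(rng) < 1e-9) rng <- rng + c(-0.5, 0.5)
      br <- seq(rng[1], rng[2], length.out = n_bins + 1)
      h <- graphics::hist(vv, breaks = br, plot = FALSE)
      hist_rows[[g]] <- tibble::tibble(
        position = pos[sel][1], parameter = par, bin_mid = h$mids,
        count = h$counts)
    }
  }
  list(summary = dplyr::bind_rows(summ),
       histogram = dplyr::bind_rows(hist_rows))
}
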