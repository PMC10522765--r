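#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the optimal proper rotation and translation mapping the selected
#' atoms of `mobile` onto those of `reference`, applies the transform to all
#' atoms of `mobile`, and reports the post-fit RMSD over the selection.
#' Reflections are forbidden: the rotation determinant is corrected to +1.
#'
#' @param mobile `n_atoms x 3` coordinate matrix to transform.
#' @param reference `n_atoms x 3` reference coordinates (must cover the
#'   selection).
#' @param selection Atom indices to fit (and measure) on; default all atoms.
#' @return List with `coords` (transformed mobile, all atoms), `rmsd`
#'   (Angstrom, over the selection), `rotation` (3x3), `translation`
#'   (length 3): the transform is `x %*% t(R) + t`.
#' @export
superpose <- function(mobile, reference, selection = NULL) {
  if (is.null(selection)) selection <- seq_len(nrow(mobile))
  sel <- sort(unique(as.integer(selection)))
  if (length(sel) < 3) stop("ill-conditioned fit: need at least 3 atoms")
  if (max(sel) > nrow(mobile) || max(sel) > nrow(reference)) {
    stop("selection exceeds frame size")
  }
  A <- mobile[sel, , drop = FALSE]
  B <- reference[sel, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  H <- t(A0) %*% B0
  sv <- svd(H)
  if (sv$d[2] < 1e-10) {
    stop("ill-conditioned fit: selected atoms are (nearly) collinear")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- cb - as.numeric(R %*% ca)
  out <- mobile %*% t(R)
  out <- sweep(out, 2, tr, FUN = "+")
  rmsd <- sqrt(mean(rowSums((out[sel, , drop = FALSE] - B)^2)))
  list(coords = out, rmsd = rmsd, rotation = R, translation = tr)
}

#' RMSD between two frames over a selection (no fitting)
#' @param a,b `n x 3` coordinate matrices.
#' @param selection Atom indices; default all.
#' @return RMSD in Angstrom.
#' @export
rmsd_raw <- function(a, b, selection = NULL) {
  if (is.null(selection)) selection <- seq_len(nrow(a))
  sel <- as.integer(selection)
  sqrt(mean(rowSums((a[sel, , drop = FALSE] - b[sel, , drop = FALSE])^2)))
}

#' Iteratively converged trajectory-average structure
#'
#' All frames are superposed on the current mean over the selection, the mean
#' is recomputed, and the cycle repeats until the mean moves less than `tol`
#' (max per-atom displacement over the selection).
#'
#' @param traj A [traj_ensemble] with at least 2 frames.
#' @param selection Atom selection to fit on; default all atoms.
#' @param tol Convergence tolerance in Angstrom (default `1e-4`).
#' @param max_iter Iteration cap (default 100).
#' @return List with `coords` (`n_atoms x 3` average structure), `iterations`,
#'   and `fitted` (a [traj_ensemble] of the superposed frames).
#' @export
compute_average_structure <- function(traj, selection = NULL, tol = 1e-4,
                                      max_iter = 100) {
  if (n_frames(traj) < 2) stop("need at least 2 frames to average")
  if (is.null(selection)) selection <- seq_len(n_atoms(traj$system))
  sel <- validate_selection(traj$system, selection)
  xyz <- traj$xyz
  mean_xyz <- colMeans(xyz)
  for (it in seq_len(max_iter)) {
    ref <- xyz_to_coords(mean_xyz)
    for (f in seq_len(nrow(xyz))) {
      fit <- superpose(xyz_to_coords(xyz[f, ]), ref, sel)
      xyz[f, ] <- coords_to_xyz(fit$coords)
    }
    new_mean <- colMeans(xyz)
    disp <- sqrt(rowSums((xyz_to_coords(new_mean)[sel, , drop = FALSE] -
                          xyz_to_coords(mean_xyz)[sel, , drop = FALSE])^2))
    mean_xyz <- new_mean
    if (max(disp) < tol) {
      return(list(coords = xyz_to_coords(mean_xyz), iterations = it,
                  fitted = traj_ensemble(traj$system, xyz, traj$times)))
    }
  }
  stop("average structure did not converge in ", max_iter,
       " iterations (last displacement ", signif(max(disp), 3), " A)")
}

#' Frame-wise RMSD series against a reference structure
#'
#' Each frame is superposed on the reference over the selection before the
#' RMSD is measured over the same selection (the production convention is to
#' fit and measure on heavy atoms of the nucleic acid, against the converged
#' average structure).
#'
#' @param traj A [traj_ensemble].
#' @param reference `n_atoms x 3` reference coordinates.
#' @param selection Atom selection; default all atoms.
#' @return Tibble with columns `frame`, `time`, `rmsd` (Angstrom).
#' @export
rmsd_series <- function(traj, reference, selection = NULL) {
  if (is.null(selection)) selection <- seq_len(n_atoms(traj$system))
  sel <- validate_selection(traj$system, selection)
  if (max(sel) > nrow(reference)) stop("reference does not cover selection")
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    superpose(frame_coords(traj, f), reference, sel)$rmsd
  }, numeric(1))
  tibble::tibble(frame = seq_len(n_frames(traj)), time = traj$times,
                 rmsd = vals)
}
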