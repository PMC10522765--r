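#' Principal component analysis of a trajectory
#'
#' Frames are superposed on the iteratively converged average structure over
#' `fit_selection`; the positional covariance of `analysis_selection` is then
#' eigen-decomposed.  The two production protocols are
#' protocol (1): `fit = nucleic heavy atoms`, `analysis = complex heavy
#' atoms`; protocol (2): `fit = analysis = nucleic heavy atoms` — i.e. the
#' superposition is on the nucleic acids in both.  Heavy-atom filtering is
#' the caller's job via the selections.  The covariance is not mass-weighted
#' (set `mass_weighted = TRUE` to fold in masses).
#'
#' Sign convention: each eigenvector's largest-magnitude component is made
#' positive, so reports are reproducible.
#'
#' @param traj A [traj_ensemble].
#' @param fit_selection Atom selection to superpose on.
#' @param analysis_selection Atom selection whose covariance is analysed.
#' @param mass_weighted Mass-weight the covariance (default `FALSE`).
#' @return A `pca_result`: list with `eigenvalues` (A^2, descending),
#'   `eigenvectors` (3M x 3M, columns are modes), `variance_fraction`,
#'   `cumulative_fraction`, `mean` (3M vector), `trace`, `fitted`
#'   ([traj_ensemble] of superposed frames), `fit_selection`,
#'   `analysis_selection`.
#' @export
pca_protocol <- function(traj, fit_selection, analysis_selection,
                         mass_weighted = FALSE) {
  fit_sel <- validate_selection(traj$system, fit_selection)
  ana_sel <- validate_selection(traj$system, analysis_selection)
  if (3 * max(ana_sel) > ncol(traj$xyz)) {
    stop("analysis selection larger than frame")
  }
  spread <- max(apply(traj$xyz, 2, function(v) diff(range(v))))
  fitted <- if (spread > 1e-12) {
    compute_average_structure(traj, fit_sel)$fitted
  } else traj
  cols <- as.numeric(t(outer(ana_sel - 1, 1:3, function(i, k) 3 * i + k)))
  X <- fitted$xyz[, cols, drop = FALSE]
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc) / nrow(Xc)
  C <- (C + t(C)) / 2
  w <- NULL
  if (mass_weighted) {
    masses <- traj$system$atoms$mass[ana_sel]
    if (anyNA(masses)) {
      masses <- lookup_element_value(ELEMENT_MASSES,
                                     traj$system$atoms$element[ana_sel], 12.011)
    }
    w <- sqrt(rep(masses, each = 3))
    C <- C * outer(w, w)
  }
  eg <- eigen(C, symmetric = TRUE)
  vals <- eg$values
  if (any(vals < -1e-10 * max(abs(vals), 1))) {
    stop("covariance not positive semidefinite")
  }
  vals <- pmax(vals, 0)
  vecs <- eg$vectors
  for (k in seq_len(ncol(vecs))) {
    imax <- which.max(abs(vecs[, k]))
    if (vecs[imax, k] < 0) vecs[, k] <- -vecs[, k]
  }
  tot <- sum(vals)
  structure(list(
    eigenvalues = vals, eigenvectors = vecs,
    variance_fraction = if (tot > 0) vals / tot else vals * 0,
    cumulative_fraction = if (tot > 0) cumsum(vals) / tot else vals * 0,
    mean = mu, trace = sum(diag(C)), fitted = fitted,
    mass_weighted = mass_weighted,
    fit_selection = fit_sel, analysis_selection = ana_sel),
    class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- min(3, length(x$eigenvalues))
  cat("<pca_result> ", length(x$analysis_selection), " atoms, ",
      n_frames(x$fitted), " frames; top-", k, " variance fraction ",
      sprintf("%.1f%%", 100 * sum(x$variance_fraction[seq_len(k)])), "\n",
      sep = "")
  invisible(x)
}

#' Project trajectory frames onto principal modes
#'
#' Centers the (already superposed) analysis coordinates and projects them on
#' the requested eigenvectors.  On the frames the PCA was fitted to, the
#' amplitude variance of mode k equals eigenvalue k and distinct modes are
#' uncorrelated.
#'
#' @param traj A [traj_ensemble] (default: the fitted frames stored in
#'   `result`).
#' @param result A `pca_result` from the same selections.
#' @param n_modes Number of leading modes to project on.
#' @return Tibble with columns `frame`, `time`, `mode`, `amplitude` (A).
#' @export
pca_project <- function(result, traj = NULL, n_modes = 3) {
  if (n_modes < 1 || n_modes > length(result$eigenvalues)) {
    stop("mode index out of range (1..", length(result$eigenvalues), ")")
  }
  if (is.null(traj)) traj <- result$fitted
  ana_sel <- result$analysis_selection
  cols <- as.numeric(t(outer(ana_sel - 1, 1:3, function(i, k) 3 * i + k)))
  Xc <- sweep(traj$xyz[, cols, drop = FALSE], 2, result$mean)
  amp <- Xc %*% result$eigenvectors[, seq_len(n_modes), drop = FALSE]
  tibble::tibble(
    frame = rep(seq_len(nrow(amp)), times = n_modes),
    time = rep(traj$times, times = n_modes),
    mode = rep(seq_len(n_modes), each = nrow(amp)),
    amplitude = as.numeric(amp))
}

#' Synthetic trajectory animating one principal mode
#'
#' Generates frames `mean + a * eigenvector` for `n_frames` amplitudes `a`
#' spanning `amplitude_range`, suitable for writing as a multi-model PDB
#' (mode "movies").  Atoms outside the analysis selection stay at the mean
#' structure of the fitted trajectory.
#'
#' @param result A `pca_result`.
#' @param mode Mode index (eigenvalue must be positive).
#' @param amplitude_range Length-2 numeric range of amplitudes (A).
#' @param n_frames Number of frames (default 21).
#' @return A [traj_ensemble] over the full system.
#' @export
mode_animation <- function(result, mode, amplitude_range = NULL,
                           n_frames = 21) {
  if (mode < 1 || mode > length(result$eigenvalues)) {
    stop("mode index out of range")
  }
  if (result$eigenvalues[mode] <= 0) {
    stop("mode ", mode, " has zero eigenvalue: no motion to animate")
  }
  if (is.null(amplitude_range)) {
    a <- 2 * sqrt(result$eigenvalues[mode])
    amplitude_range <- c(-a, a)
  }
  amps <- seq(amplitude_range[1], amplitude_range[2], length.out = n_frames)
  system <- result$fitted$system
  base_xyz <- colMeans(result$fitted$xyz)
  ana_sel <- result$analysis_selection
  cols <- as.numeric(t(outer(ana_sel - 1, 1:3, function(i, k) 3 * i + k)))
  base_xyz[cols] <- result$mean
  vec <- result$eigenvectors[, mode]
  xyz <- matrix(rep(base_xyz, each = n_frames), nrow = n_frames)
  xyz[, cols] <- xyz[, cols] + outer(amps, vec)
  traj_ensemble(system, xyz)
}

#' Write PCA results as CSV
#'
#' Writes `<prefix>_spectrum.csv` (eigenvalues and variance fractions) and
#' `<prefix>_projections.csv` (per-frame amplitudes of the leading modes).
#'
#' @param result A `pca_result`.
#' @param prefix Output path prefix.
#' @param n_modes Modes to project (default 3).
#' @export
write_pca_result <- function(result, prefix, n_modes = 3) {
  p1 <- paste0(prefix, "_spectrum.csv")
  p2 <- paste0(prefix, "_projections.csv")
  utils::write.csv(tidy.pca_result(result), p1, row.names = FALSE)
  n_modes <- min(n_modes, length(result$eigenvalues))
  utils::write.csv(pca_project(result, n_modes = n_modes), p2,
                   row.names = FALSE)
  invisible(c(p1, p2))
}
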