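#' Positional covariance of a trajectory selection
#'
#' Computes the covariance of the Cartesian coordinates of the selected atoms
#' about their mean.  By default every frame is first superposed on the
#' iteratively converged average structure over the same selection, removing
#' rigid-body translation/rotation (without this, diffusion inflates the
#' apparent configurational entropy meaninglessly).  Masses are attached but
#' not folded in; mass weighting happens in [schlitter_entropy()].
#'
#' @param traj A [traj_ensemble] with at least 2 frames.
#' @param selection Atom selection (e.g. backbone P atoms).
#' @param superpose_first Remove rigid-body motion first (default `TRUE`).
#' @return A `covariance_model`: list with `mean` (3N vector, A), `cov`
#'   (3N x 3N matrix, A^2), `masses` (per atom, amu), `n_frames`,
#'   `superposed`, `selection`.
#' @export
mass_weighted_covariance <- function(traj, selection = NULL,
                                     superpose_first = TRUE) {
  if (n_frames(traj) < 2) stop("need at least 2 frames for a covariance")
  if (is.null(selection)) selection <- seq_len(n_atoms(traj$system))
  sel <- validate_selection(traj$system, selection)
  cols <- as.numeric(t(outer(sel - 1, 1:3, function(i, k) 3 * i + k)))
  if (superpose_first) {
    # frozen trajectories have zero spread; skip the (singular) fit
    spread <- max(apply(traj$xyz[, cols, drop = FALSE], 2,
                        function(v) diff(range(v))))
    if (spread > 1e-12) {
      traj <- compute_average_structure(traj, sel)$fitted
    }
  }
  X <- traj$xyz[, cols, drop = FALSE]
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc) / nrow(Xc)   # population covariance
  C <- (C + t(C)) / 2
  masses <- traj$system$atoms$mass[sel]
  if (anyNA(masses)) {
    masses <- lookup_element_value(ELEMENT_MASSES,
                                   traj$system$atoms$element[sel], 12.011)
  }
  structure(list(mean = mu, cov = C, masses = masses,
                 n_frames = n_frames(traj), superposed = superpose_first,
                 selection = sel),
            class = "covariance_model")
}

#' Covariance model from an explicit matrix
#'
#' Wraps a known covariance (e.g. the generating covariance of a synthetic
#' Gaussian trajectory) so the closed-form Schlitter value can be computed.
#'
#' @param cov 3N x 3N covariance matrix (A^2).
#' @param masses Per-atom masses, amu (length N).
#' @return A `covariance_model`.
#' @export
covariance_model <- function(cov, masses) {
  stopifnot(nrow(cov) == ncol(cov), nrow(cov) == 3 * length(masses))
  structure(list(mean = rep(0, nrow(cov)), cov = (cov + t(cov)) / 2,
                 masses = masses, n_frames = NA_integer_, superposed = NA,
                 selection = NULL),
            class = "covariance_model")
}

#' Schlitter configurational entropy (reported as TS, kcal/mol)
#'
#' Schlitter's upper-bound estimate
#' \deqn{S = (k_B/2) \ln\det[ I + (k_B T e^2/\hbar^2) M^{1/2} \sigma M^{1/2} ]}
#' with \eqn{\sigma} the positional covariance, \eqn{M} the diagonal mass
#' matrix and \eqn{e} Euler's number, evaluated through the eigenvalues
#' \eqn{\lambda_i} (amu A^2) of the mass-weighted covariance:
#' \deqn{TS = (k_B T/2) \sum_i \ln(1 + \alpha \lambda_i)},
#' \eqn{\alpha = k_B T e^2/\hbar^2} expressed per amu A^2 (dimensionless
#' product; at 300 K \eqn{\alpha \approx 45.7}).  The result is returned as
#' the product TS in kcal/mol.
#'
#' @param cov A `covariance_model`.
#' @param temperature Temperature in K (default 300).
#' @param eig_tol Eigenvalues below `-eig_tol` abort; within `[-eig_tol, 0)`
#'   they are clamped to 0 (default `1e-10` relative to the largest).
#' @return TS in kcal/mol (>= 0).
#' @export
schlitter_entropy <- function(cov, temperature = 300, eig_tol = 1e-10) {
  m3 <- rep(cov$masses, each = 3)
  D <- sqrt(m3)
  MW <- cov$cov * outer(D, D)     # M^{1/2} C M^{1/2}
  ev <- eigen(MW, symmetric = TRUE, only.values = TRUE)$values
  scale <- max(abs(ev), 1)
  if (any(ev < -eig_tol * scale)) {
    stop("covariance has negative eigenvalue beyond tolerance: ", min(ev))
  }
  ev <- pmax(ev, 0)
  alpha <- schlitter_alpha(temperature)
  0.5 * nuctraj_constants$kB * temperature * sum(log1p(alpha * ev))
}

#' Windowed Schlitter entropy of a trajectory
#'
#' Computes TS from all analysed frames (`TS_full`) and from consecutive
#' non-overlapping windows of length `window_length` ps (`TS_windows`).  The
#' reported `sd` is the standard deviation over the window estimates; the
#' production protocol uses 100 ns windows of a 500 ns analysis span, giving
#' five window values.  `sd_incl_full` additionally includes the
#' full-trajectory value in the spread (both conventions are reported since
#' either reading of "windows" is defensible).
#'
#' @param traj A [traj_ensemble] (equilibration discarded).
#' @param selection Atom selection (e.g. P atoms).
#' @param temperature K (default 300).
#' @param window_length Window length in ps.
#' @param superpose_first Remove rigid-body motion (default `TRUE`).
#' @return An `entropy_result`: list with `TS_full`, `TS_windows`, `sd`,
#'   `sd_incl_full`, `temperature`, `n_frames`, `selection`, `windows`
#'   (tibble with window start/end times and TS).
#' @export
windowed_entropy <- function(traj, selection = NULL, temperature = 300,
                             window_length, superpose_first = TRUE) {
  if (is.null(selection)) selection <- seq_len(n_atoms(traj$system))
  sel <- validate_selection(traj$system, selection)
  t0 <- traj$times[1]
  span <- max(traj$times) - t0
  n_win <- floor((span + (traj$times[2] - traj$times[1])) / window_length)
  edges <- t0 - (traj$times[2] - traj$times[1]) + window_length * (0:n_win)
  win_id <- findInterval(traj$times, edges, left.open = TRUE,
                         rightmost.closed = FALSE)
  win_id[win_id > n_win] <- NA
  if (sum(!is.na(unique(win_id))) < 2) {
    stop("window_length must fit at least twice into the analysed span")
  }
  ts_full <- schlitter_entropy(
    mass_weighted_covariance(traj, sel, superpose_first), temperature)
  wins <- sort(unique(win_id[!is.na(win_id)]))
  ts_w <- vapply(wins, function(w) {
    keep <- which(!is.na(win_id) & win_id == w)
    sub <- traj_ensemble(traj$system, traj$xyz[keep, , drop = FALSE],
                         traj$times[keep])
    schlitter_entropy(mass_weighted_covariance(sub, sel, superpose_first),
                      temperature)
  }, numeric(1))
  windows <- tibble::tibble(
    window = seq_along(wins),
    t_start = vapply(wins, function(w) min(traj$times[!is.na(win_id) & win_id == w]), 1),
    t_end = vapply(wins, function(w) max(traj$times[!is.na(win_id) & win_id == w]), 1),
    TS = ts_w)
  structure(list(TS_full = ts_full, TS_windows = ts_w,
                 sd = stats::sd(ts_w),
                 sd_incl_full = stats::sd(c(ts_w, ts_full)),
                 temperature = temperature, n_frames = n_frames(traj),
                 selection = sel, windows = windows),
            class = "entropy_result")
}

#' @export
print.entropy_result <- function(x, ...) {
  cat("<entropy_result> TS = ", sprintf("%.3f", x$TS_full), " +/- ",
      sprintf("%.3f", x$sd), " kcal/mol at ", x$temperature, " K (",
      length(x$TS_windows), " windows, ", x$n_frames, " frames, ",
      length(x$selection), " atoms)\n", sep = "")
  invisible(x)
}

#' Write an entropy result as JSON (+ eigenvalue audit CSV)
#' @param er An `entropy_result`.
#' @param prefix Output path prefix.
#' @export
write_entropy_result <- function(er, prefix) {
  p <- paste0(prefix, ".json")
  jsonlite::write_json(list(
    selection_n_atoms = length(er$selection), temperature = er$temperature,
    TS_full = er$TS_full, TS_windows = er$TS_windows, sd = er$sd,
    sd_incl_full = er$sd_incl_full, n_frames = er$n_frames),
    p, auto_unbox = TRUE, digits = NA)
  invisible(p)
}
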