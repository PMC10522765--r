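#' Pairwise Coulomb and Lennard-Jones energy
#'
#' Coulomb: `ke * qi * qj / r` with `ke = 332.0637` kcal A / (mol e^2).
#' Lennard-Jones: `4 eps [(sigma/r)^12 - (sigma/r)^6]`.  Combination rules
#' are Lorentz-Berthelot: `sigma_ij = (sigma_i + sigma_j)/2`,
#' `eps_ij = sqrt(eps_i * eps_j)` (applied by the group evaluators).
#'
#' @param r Distance(s), Angstrom (> 0).
#' @param qi,qj Partial charges, e.
#' @param sigma_ij Combined LJ sigma, A.
#' @param epsilon_ij Combined LJ epsilon, kcal/mol.
#' @return List with numeric vectors `coulomb` and `lj` (kcal/mol).
#' @export
pair_energy <- function(r, qi, qj, sigma_ij, epsilon_ij) {
  if (any(r <= 0)) stop("pair distance must be positive")
  sr6 <- (sigma_ij / r)^6
  list(coulomb = nuctraj_constants$ke * qi * qj / r,
       lj = 4 * epsilon_ij * (sr6^2 - sr6))
}

#' Group-group specification for interaction energies
#'
#' @param name Label for the pairing.
#' @param group_a,group_b Disjoint atom selections.
#' @param cutoff Short-range cutoff in A (default 10).
#' @return A `group_pair_spec` list.
#' @export
group_pair_spec <- function(name, group_a, group_b, cutoff = 10.0) {
  stopifnot(cutoff > 0)
  if (length(intersect(as.integer(group_a), as.integer(group_b))) > 0) {
    stop("group_a and group_b must be disjoint")
  }
  structure(list(name = name, group_a = as.integer(group_a),
                 group_b = as.integer(group_b), cutoff = cutoff),
            class = "group_pair_spec")
}

#' Short-range group-group interaction energy for one frame
#'
#' Sums [pair_energy()] over all cross pairs with `r <= cutoff`.  Truncation
#' is plain: no switching function and no long-range correction, matching the
#' qualitative short-range convention of GROMACS-style energy groups.
#'
#' @param coords `n_atoms x 3` frame coordinates.
#' @param system A parameterized [mol_system].
#' @param spec A [group_pair_spec].
#' @return Named numeric vector `c(coulomb = ..., lj = ...)` in kcal/mol.
#' @export
group_interaction_energy <- function(coords, system, spec) {
  a <- system$atoms
  ga <- spec$group_a; gb <- spec$group_b
  pars <- c(a$charge[ga], a$charge[gb], a$lj_sigma[ga], a$lj_sigma[gb],
            a$lj_epsilon[ga], a$lj_epsilon[gb])
  if (anyNA(pars)) {
    stop("unparameterized atom(s) in energy groups; run load_parameters()")
  }
  pa <- coords[ga, , drop = FALSE]
  pb <- coords[gb, , drop = FALSE]
  # all cross distances (na x nb)
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
  d <- sqrt(pmax(d2, 0))
  within <- d <= spec$cutoff & d > 0
  if (!any(within)) return(c(coulomb = 0, lj = 0))
  idx <- which(within, arr.ind = TRUE)
  i <- ga[idx[, 1]]; j <- gb[idx[, 2]]
  rij <- d[within]
  if (any(rij < 1e-6)) stop("coincident atoms in energy evaluation (r = 0)")
  e <- pair_energy(rij, a$charge[i], a$charge[j],
                   (a$lj_sigma[i] + a$lj_sigma[j]) / 2,
                   sqrt(a$lj_epsilon[i] * a$lj_epsilon[j]))
  c(coulomb = sum(e$coulomb), lj = sum(e$lj))
}

#' Specific/nonspecific interaction-energy decomposition of a trajectory
#'
#' Evaluates three role-derived group pairings per frame:
#' \describe{
#'   \item{specific}{nucleobase atoms x protein side-chain atoms}
#'   \item{nonspecific_backbone_vs_protein}{nucleic backbone x all protein atoms}
#'   \item{nonspecific_proteinbackbone_vs_bases}{protein backbone x nucleobase atoms}
#' }
#' plus their sum as `total`.  The three pairings partition all intermolecular
#' protein-nucleic atom pairs, so `total` is the full short-range
#' protein-nucleic interaction energy.
#'
#' @param traj A [traj_ensemble]; roles classified, parameters loaded,
#'   equilibration discarded.
#' @param cutoff Short-range cutoff in A (default 10).
#' @return An `energy_decomposition`: list with `per_frame` (tibble: `frame`,
#'   `time`, `group`, `coulomb`, `lj`, `total`) and `summary` (tibble of
#'   trajectory means and SDs per group and component).
#' @export
decompose_interaction_energy <- function(traj, cutoff = 10.0) {
  system <- traj$system
  base    <- select_atoms(system, role = "base")
  nbb     <- select_atoms(system, role = "nucleic_backbone")
  side    <- select_atoms(system, role = "protein_sidechain")
  pbb     <- select_atoms(system, role = "protein_backbone")
  protein <- atom_selection(c(side, pbb), "all protein atoms")
  specs <- list(
    group_pair_spec("specific", base, side, cutoff),
    group_pair_spec("nonspecific_backbone_vs_protein", nbb, protein, cutoff),
    group_pair_spec("nonspecific_proteinbackbone_vs_bases", pbb, base, cutoff)
  )
  nf <- n_frames(traj)
  rows <- vector("list", nf * length(specs))
  k <- 0
  for (f in seq_len(nf)) {
    coords <- frame_coords(traj, f)
    for (s in specs) {
      e <- group_interaction_energy(coords, system, s)
      k <- k + 1
      rows[[k]] <- tibble::tibble(frame = f, time = traj$times[f],
                                  group = s$name,
                                  coulomb = e[["coulomb"]], lj = e[["lj"]])
    }
  }
  per_frame <- dplyr::bind_rows(rows)
  totals <- per_frame |>
    dplyr::group_by(.data$frame, .data$time) |>
    dplyr::summarise(group = "total", coulomb = sum(.data$coulomb),
                     lj = sum(.data$lj), .groups = "drop")
  per_frame <- dplyr::bind_rows(per_frame, totals)
  per_frame$total <- per_frame$coulomb + per_frame$lj
  summary <- per_frame |>
    tidyr::pivot_longer(c("coulomb", "lj", "total"), names_to = "component",
                        values_to = "energy") |>
    dplyr::group_by(.data$group, .data$component) |>
    dplyr::summarise(mean = mean(.data$energy),
                     sd = stats::sd(.data$energy), .groups = "drop")
  structure(list(per_frame = per_frame, summary = summary,
                 cutoff = cutoff, n_frames = nf),
            class = "energy_decomposition")
}

#' @export
print.energy_decomposition <- function(x, ...) {
  cat("<energy_decomposition> ", x$n_frames, " frames, cutoff ", x$cutoff,
      " A\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Write an energy decomposition as CSV + JSON
#' @param ed An `energy_decomposition`.
#' @param prefix Output path prefix.
#' @export
write_energy_decomposition <- function(ed, prefix) {
  p1 <- paste0(prefix, "_per_frame.csv")
  p2 <- paste0(prefix, "_summary.json")
  utils::write.csv(ed$per_frame, p1, row.names = FALSE)
  jsonlite::write_json(list(cutoff = ed$cutoff, n_frames = ed$n_frames,
                            summary = ed$summary),
                       p2, auto_unbox = TRUE, digits = NA)
  invisible(c(p1, p2))
}
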