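#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a PCA result
#'
#' One row per mode: eigenvalue (A^2), variance fraction and cumulative
#' fraction.
#'
#' @param x A `pca_result`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy pca_result
#' @export
tidy.pca_result <- function(x, ...) {
  tibble::tibble(mode = seq_along(x$eigenvalues),
                 eigenvalue = x$eigenvalues,
                 variance_fraction = x$variance_fraction,
                 cumulative_fraction = x$cumulative_fraction)
}

#' @rdname tidy.pca_result
#' @method glance pca_result
#' @export
glance.pca_result <- function(x, ...) {
  tibble::tibble(n_frames = n_frames(x$fitted),
                 n_atoms = length(x$analysis_selection),
                 trace = x$trace,
                 top3_fraction = sum(x$variance_fraction[1:min(3, length(x$variance_fraction))]))
}

#' Tidy an entropy result
#'
#' One row per window, with the full-trajectory estimate in `glance()`.
#'
#' @param x An `entropy_result`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy entropy_result
#' @export
tidy.entropy_result <- function(x, ...) x$windows

#' @rdname tidy.entropy_result
#' @method glance entropy_result
#' @export
glance.entropy_result <- function(x, ...) {
  tibble::tibble(TS_full = x$TS_full, sd = x$sd,
                 sd_incl_full = x$sd_incl_full,
                 temperature = x$temperature, n_frames = x$n_frames,
                 n_windows = length(x$TS_windows),
                 n_atoms = length(x$selection))
}

#' Tidy a contact map
#'
#' The residue-pair strength table (`tidy()`) and run-level counts
#' (`glance()`).
#'
#' @param x A `contact_map`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy contact_map
#' @export
tidy.contact_map <- function(x, ...) x$map

#' @rdname tidy.contact_map
#' @method glance contact_map
#' @export
glance.contact_map <- function(x, ...) {
  tibble::tibble(n_frames = x$n_frames,
                 n_candidate_events = nrow(x$events),
                 n_observed_events = sum(x$events$occupancy > 0),
                 n_persistent_events = sum(x$events$kept & x$events$occupancy > 0),
                 persistence = x$persistence)
}

#' Tidy an energy decomposition
#'
#' The per-group mean/SD summary (`tidy()`) and run facts (`glance()`).
#'
#' @param x An `energy_decomposition`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy energy_decomposition
#' @export
tidy.energy_decomposition <- function(x, ...) x$summary

#' @rdname tidy.energy_decomposition
#' @method glance energy_decomposition
#' @export
glance.energy_decomposition <- function(x, ...) {
  tibble::tibble(n_frames = x$n_frames, cutoff = x$cutoff)
}
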