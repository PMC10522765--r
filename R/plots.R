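#' Plot a contact map as per-residue strength bars
#'
#' Mean contact strength with SD error bars per protein residue, split
#' specific vs nonspecific (the conventional presentation of dynamic contact
#' maps).
#'
#' @param object A `contact_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot contact_map
#' @export
autoplot.contact_map <- function(object, ...) {
  df <- object$map |>
    dplyr::group_by(.data$protein_res, .data$protein_resname, .data$class) |>
    dplyr::summarise(mean_strength = sum(.data$mean_strength),
                     sd = sqrt(sum(.data$sd^2)), .groups = "drop") |>
    dplyr::mutate(residue = paste0(.data$protein_resname, .data$protein_res))
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$residue, .data$protein_res),
    y = .data$mean_strength, fill = .data$class)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = pmax(.data$mean_strength - .data$sd, 0),
      ymax = .data$mean_strength + .data$sd),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25) +
    ggplot2::scale_fill_manual(values = c(specific = "#3366bb",
                                          nonspecific = "#ee8833")) +
    ggplot2::labs(x = "protein residue", y = "mean contact strength",
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Scree plot of a PCA result
#'
#' @param object A `pca_result`.
#' @param n_modes Modes to show (default 10).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pca_result
#' @export
autoplot.pca_result <- function(object, n_modes = 10, ...) {
  df <- tidy.pca_result(object)
  df <- df[seq_len(min(n_modes, nrow(df))), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$mode, .data$variance_fraction)) +
    ggplot2::geom_col(fill = "#3366bb") +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative_fraction)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$cumulative_fraction)) +
    ggplot2::labs(x = "principal component", y = "variance fraction") +
    ggplot2::theme_minimal()
}

#' Plot an RMSD series
#'
#' @param series Tibble from [rmsd_series()].
#' @return A ggplot object.
#' @export
plot_rmsd_series <- function(series) {
  ggplot2::ggplot(series, ggplot2::aes(.data$time / 1000, .data$rmsd)) +
    ggplot2::geom_line(colour = "#3366bb") +
    ggplot2::labs(x = "time (ns)", y = "RMSD (Å)") +
    ggplot2::theme_minimal()
}

#' Plot per-step helical parameter profiles
#'
#' Mean +/- SD per step for each parameter of a
#' [parameter_series_summary()] output.
#'
#' @param summary The `summary` tibble from [parameter_series_summary()].
#' @return A ggplot object.
#' @export
plot_step_parameters <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(.data$position, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         fill = "#3366bb", alpha = 0.25) +
    ggplot2::geom_line(colour = "#3366bb") +
    ggplot2::geom_point(colour = "#3366bb") +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "step / level", y = NULL) +
    ggplot2::theme_minimal()
}
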