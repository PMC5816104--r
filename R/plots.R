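#' Plot a BS energy table
#'
#' Dot plot of relative state energies, one panel per energy column, with
#' states ordered by their resting-column energy.  Missing (unconverged)
#' states are omitted.
#'
#' @param object A `bs_energy_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bs_energy_table <- function(object, ...) {
  df <- dplyr::filter(object, !is.na(.data$energy_kjmol))
  ord <- df |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(e = min(.data$energy_kjmol), .groups = "drop") |>
    dplyr::arrange(.data$e)
  df$label <- factor(df$label, levels = ord$label)
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = .data$energy_kjmol, y = .data$label,
      colour = .data$family
    )
  ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~column) +
    ggplot2::labs(
      x = "relative energy (kJ/mol)", y = NULL,
      colour = "fixed cluster"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a reaction profile
#'
#' Classic stationary-point ladder: horizontal levels connected in
#' mechanism order.
#'
#' @param object A `reaction_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reaction_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$step <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$energy_kjmol)) +
    ggplot2::geom_segment(
      ggplot2::aes(
        x = .data$step - 0.3, xend = .data$step + 0.3,
        yend = .data$energy_kjmol
      ),
      linewidth = 1.2
    ) +
    ggplot2::geom_line(linetype = "dotted", colour = "grey50") +
    ggplot2::geom_text(
      ggplot2::aes(label = .data$label),
      vjust = -0.8, size = 3
    ) +
    ggplot2::scale_x_continuous(breaks = NULL) +
    ggplot2::labs(x = NULL, y = "relative energy (kJ/mol)") +
    ggplot2::theme_minimal()
}

#' Plot a constrained scan
#'
#' Relaxed energy against the scanned distance; unconverged points are
#' hollow.
#'
#' @param object An `fes_scan` from [constrained_scan()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fes_scan <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$coordinate_A, y = .data$energy_kjmol)
  ) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$converged), size = 2) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::labs(
      x = "constrained distance (Å)",
      y = "relaxed energy (kJ/mol)", shape = "converged"
    ) +
    ggplot2::theme_minimal()
}

#' Compare two mechanisms graphically
#'
#' Overlays two profiles on a shared energy axis.
#'
#' @param profile_a,profile_b Two `reaction_profile`s.
#' @param names Length-2 labels for the legend.
#' @return A ggplot object.
#' @export
plot_mechanism_comparison <- function(profile_a, profile_b,
                                      names = c("mechanism 1", "mechanism 2")) {
  df <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(profile_a), mechanism = names[1]),
    dplyr::mutate(tibble::as_tibble(profile_b), mechanism = names[2])
  ) |>
    dplyr::group_by(.data$mechanism) |>
    dplyr::mutate(step = dplyr::row_number()) |>
    dplyr::ungroup()
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = .data$step, y = .data$energy_kjmol,
      colour = .data$mechanism
    )
  ) +
    ggplot2::geom_line(linetype = "dotted") +
    ggplot2::geom_segment(
      ggplot2::aes(
        x = .data$step - 0.3, xend = .data$step + 0.3,
        yend = .data$energy_kjmol
      ),
      linewidth = 1.2
    ) +
    ggplot2::geom_text(
      ggplot2::aes(label = .data$label),
      vjust = -0.8, size = 3, show.legend = FALSE
    ) +
    ggplot2::labs(x = NULL, y = "relative energy (kJ/mol)") +
    ggplot2::theme_minimal()
}
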