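# ggplot2 views of the result tables: RMSD trends against the number of
# explicit solvent molecules, discrimination bars against the precision
# window, relative-energy profiles, and stick-spectrum comparisons.

model_level <- function(model) {
  lv <- suppressWarnings(as.integer(sub("^[A-Za-z]+-(\\d+).*$", "\\1", model)))
  lv
}

#' RMSD trend across solvation models
#'
#' One line per conformer; when model ids encode the number of explicit
#' solvent molecules (e.g. `PCM-15CHCl3`) the x axis is that count,
#' otherwise the model id itself.
#'
#' @param rmsd a tibble from [conformer_rmsd()] (optionally with a `family`
#'   column, used for facetting).
#' @param statistic column to draw.
#' @return a ggplot object.
#' @export
plot_rmsd_trend <- function(rmsd, statistic = "rmsd_centered") {
  lv <- model_level(rmsd$model)
  d <- rmsd |> mutate(.x = if (all(!is.na(lv))) lv else .data$model)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$.x, y = .data[[statistic]],
                                       colour = .data$conformer,
                                       group = .data$conformer)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = if (all(!is.na(lv))) "explicit solvent molecules" else "model",
                  y = paste0(statistic, " (ppm)"), colour = "conformer") +
    ggplot2::theme_minimal()
  if ("family" %in% names(d))
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$family), scales = "free_y")
  p
}

#' @method autoplot discrimination_report
#' @export
autoplot.discrimination_report <- function(object, ...) {
  ref <- attr(object, "reference")
  d <- as_tibble(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$candidate,
                                       y = .data$delta_rmsd,
                                       fill = .data$verdict)) +
    ggplot2::geom_rect(ggplot2::aes(xmin = -Inf, xmax = Inf,
                                    ymin = -.data$window, ymax = .data$window),
                       fill = "grey85", alpha = 0.4, colour = NA) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(y = expression(Delta * "(RMSD) (ppm)"),
                  x = "candidate conformer",
                  subtitle = if (!is.na(ref)) paste0("relative to ", ref) else NULL) +
    ggplot2::theme_minimal()
  facets <- intersect(c("family", "model"), names(d))
  if (length(facets) > 0L)
    p <- p + ggplot2::facet_wrap(facets, scales = "free")
  p
}

#' Relative conformer energies per model variant
#'
#' @param rel output of [relative_energies()] (rows from several models /
#'   input tags may be bound together).
#' @return a ggplot object.
#' @export
plot_relative_energies <- function(rel) {
  p <- ggplot2::ggplot(rel, ggplot2::aes(x = .data$conformer,
                                         y = .data$delta_e,
                                         fill = .data$input_tag)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "conformer",
                  y = expression(Delta * E[rel] ~ "(kcal/mol)"),
                  fill = "input") +
    ggplot2::theme_minimal()
  facets <- intersect(c("model", "variant"), names(rel))
  if (length(facets) > 0L)
    p <- p + ggplot2::facet_wrap(facets, scales = "free_y")
  p
}

#' Stick-spectrum comparison of computed and experimental shifts
#'
#' @param shifts a shift table filtered to the conformers/models to draw.
#' @param experimental the experimental table.
#' @param element `"H"` or `"C"`.
#' @return a ggplot object.
#' @export
plot_spectrum <- function(shifts, experimental, element = "H") {
  comp <- shifts |> filter(.data$element == !!element) |>
    transmute(shift = .data$shift,
              series = paste(.data$conformer, .data$model))
  labs_el <- unique(shifts$label[shifts$element == element])
  expd <- experimental |> filter(.data$label %in% labs_el) |>
    transmute(shift = .data$shift_exp, series = "experimental")
  ggplot2::ggplot(bind_rows(comp, expd),
                  ggplot2::aes(x = .data$shift, xend = .data$shift,
                               y = 0, yend = 1, colour = .data$series)) +
    ggplot2::geom_segment(alpha = 0.8) +
    ggplot2::scale_x_reverse() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$series)) +
    ggplot2::labs(x = expression(delta ~ "(ppm)"), y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   legend.position = "none")
}

#' @method autoplot recovery_result
#' @export
autoplot.recovery_result <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$rule, y = .data$recovery_rate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(ggplot2::aes(yintercept = 1 / .data$n_conformers),
                        linetype = 2) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "recovery rate",
                  caption = "dashed line: chance level") +
    ggplot2::theme_minimal()
}
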