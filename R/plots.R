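#' Score scatter of a sensitivity PCA
#'
#' Conditions plotted in the plane of two principal components, coloured by
#' sampling day and shaped by genotype (where those columns are present in
#' the scores).
#'
#' @param object A [pca_gamma()] result.
#' @param components Two component names (default PC1, PC2).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gamma_pca
#' @export
autoplot.gamma_pca <- function(object, components = c("PC1", "PC2"), ...) {
  sc <- object$scores
  stopifnot(all(components %in% names(sc)))
  ev <- 100 * object$explained[components]
  p <- ggplot2::ggplot(sc, ggplot2::aes(
    x = .data[[components[1]]], y = .data[[components[2]]]))
  if ("day" %in% names(sc)) {
    p <- p + ggplot2::aes(colour = factor(.data$day)) +
      ggplot2::labs(colour = "day")
  }
  if ("genotype" %in% names(sc)) {
    p <- p + ggplot2::aes(shape = .data$genotype)
  }
  p + ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", components[1], ev[1]),
      y = sprintf("%s (%.1f%%)", components[2], ev[2])) +
    ggplot2::theme_minimal()
}

#' Heatmap of sensitivity scores over conditions and measures
#'
#' @param gamma_tbl Sensitivity tibble from [sensitivity_sweep()].
#' @param measures Optional measure columns (defaults to all numeric
#'   non-metadata columns).
#' @return A ggplot object.
#' @export
plot_gamma_heatmap <- function(gamma_tbl, measures = NULL) {
  meta_cols <- intersect(c("genotype", "day", "condition"), names(gamma_tbl))
  if (is.null(measures)) {
    measures <- setdiff(names(gamma_tbl), meta_cols)
  }
  long <- gamma_tbl |>
    dplyr::mutate(condition = paste(.data$genotype, .data$day,
                                    sep = " / ")) |>
    tidyr::pivot_longer(dplyr::all_of(measures), names_to = "measure",
                        values_to = "gamma") |>
    dplyr::mutate(measure = factor(.data$measure, levels = measures))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$measure, y = .data$condition,
                                     fill = .data$gamma)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = expression(gamma)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Bar chart of high-control-coefficient frequencies
#'
#' @param freq_tbl Output of [high_cc_frequency()].
#' @return A ggplot object.
#' @export
plot_cc_frequency <- function(freq_tbl) {
  group <- setdiff(names(freq_tbl), "n_exceed")[1]
  ggplot2::ggplot(freq_tbl, ggplot2::aes(x = factor(.data[[group]]),
                                         y = .data$n_exceed)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = group, y = "coefficients above threshold") +
    ggplot2::theme_minimal()
}
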