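#' Plot Betti curves against edge density
#'
#' One line per homology dimension, x = edge density `j/K`, y = Betti
#' number.
#'
#' @param object a `betti_curves` object.
#' @param ... unused.
#' @return a ggplot.
#' @export
#' @method autoplot betti_curves
autoplot.betti_curves <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$density, y = .data$betti,
                                   colour = factor(.data$dimension))) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "edge density", y = "Betti number",
                  colour = "dimension") +
    ggplot2::theme_minimal()
}

#' Scatter of integral Betti signatures by stratum
#'
#' Projects a signature table onto the (B0AUC, B1AUC) plane, coloured by
#' stratum (geometry label, with hyperbolic radii split out).
#'
#' @param signatures tibble from [signature_sweep()] or
#'   [modularity_sweep()].
#' @param log_axes plot on log10 axes (default TRUE; AUCs span orders of
#'   magnitude across dimensions).
#' @return a ggplot.
#' @export
plot_signatures <- function(signatures, log_axes = TRUE) {
  df <- dplyr::mutate(signatures, stratum = ifelse(
    .data$geometry == "HG", paste0("HG R=", .data$radius), .data$geometry))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$b0_auc, y = .data$b1_auc,
                                        colour = .data$stratum)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "B0AUC", y = "B1AUC", colour = "stratum") +
    ggplot2::theme_minimal()
  if (log_axes) p <- p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  p
}

#' Heat map of a pairwise separability matrix
#'
#' @param sep result of [separability_matrix()].
#' @return a ggplot.
#' @export
plot_separability <- function(sep) {
  df <- dplyr::mutate(sep$table,
                      pair = paste(.data$geometry_a, "vs", .data$geometry_b))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$geometry_a, y = .data$geometry_b,
                                   fill = .data$accuracy)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$accuracy))) +
    ggplot2::scale_fill_gradient(limits = c(0.4, 1), low = "white", high = "steelblue") +
    ggplot2::labs(x = NULL, y = NULL, fill = "accuracy") +
    ggplot2::theme_minimal()
}
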