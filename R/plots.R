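# autoplot() methods for the main result types.

#' @export
autoplot.plr_fit <- function(object, ...) {
  df <- tibble(time_ms = object$times, volume_ul = object$volumes,
               fitted = object$fitted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$volume_ul), size = 1,
                        colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::geom_vline(xintercept = object$knot_times, linetype = 3) +
    ggplot2::labs(x = "time (ms)", y = "LV volume (ul)",
                  title = "Piecewise-linear cardiac cycle fit")
}

#' @export
autoplot.tvc_df <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_ms, y = .data$volume_ul)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "time (ms)", y = "LV volume (ul)")
}

#' @export
autoplot.segment_strain_curves <- function(object, component = c("ecc", "err"),
                                           ...) {
  component <- match.arg(component)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time,
                                       y = .data[[component]],
                                       colour = factor(.data$segment))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "cycle fraction", y = paste0(toupper(component), " (%)"),
                  colour = "segment")
}

#' @export
autoplot.ageing_pca <- function(object, colour = NULL, ...) {
  p <- ggplot2::ggplot(object$scores,
                       ggplot2::aes(x = .data$PC1, y = .data$PC2))
  if (!is.null(colour)) {
    df <- dplyr::mutate(object$scores, .colour = colour)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                          colour = .data$.colour)) +
      ggplot2::labs(colour = "group")
  }
  p + ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2]))
}

#' @export
autoplot.deg_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$logfc,
                                       y = -log10(.data$adj_p),
                                       colour = .data$is_deg)) +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p",
                  colour = "DEG")
}
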