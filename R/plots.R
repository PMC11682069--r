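#' Knee plot of ranked barcode counts
#'
#' Log-log ranked barcode plot with the calling threshold marked; the
#' standard visual for cell-versus-ambient separation.
#'
#' @param x A `knee_result` from [find_knee()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_knee <- function(x, ...) {
  stopifnot(inherits(x, "knee_result"))
  df <- tidy(x)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$reads,
                                   colour = .data$called)) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::geom_vline(xintercept = x$threshold_rank, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#1b7837", `FALSE` = "grey60")) +
    ggplot2::labs(x = "Barcode rank", y = "Reads per barcode",
                  colour = "Called cell",
                  title = sprintf("Knee at rank %d (%s reads)",
                                  x$threshold_rank, format(x$threshold_count))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.knee_result <- function(object, ...) plot_knee(object, ...)

#' Barnyard scatter of per-cell species counts
#'
#' @param x A `barnyard_report` from [classify_barnyard()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_barnyard <- function(x, ...) {
  stopifnot(inherits(x, "barnyard_report"))
  df <- x$cells
  ca <- paste0("count_", x$species[1])
  cb <- paste0("count_", x$species[2])
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[ca]], y = .data[[cb]],
                                   colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::labs(
      x = paste(x$species[1], "transcripts"),
      y = paste(x$species[2], "transcripts"),
      colour = NULL,
      title = sprintf("Observed multiplet rate %.2f%% (corrected %.2f%%)",
                      100 * x$observed_multiplet_rate,
                      100 * x$corrected_multiplet_rate)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.barnyard_report <- function(object, ...) plot_barnyard(object, ...)

#' Sequencing saturation curve plot
#'
#' @param x A `saturation_curve` from [saturation_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_saturation <- function(x, ...) {
  stopifnot(inherits(x, "saturation_curve"))
  p <- ggplot2::ggplot(x, ggplot2::aes(x = .data$center, y = .data$mean_genes)) +
    ggplot2::geom_point() +
    ggplot2::geom_line()
  if (any(!is.na(x$sd_genes))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_genes - .data$sd_genes,
                   ymax = .data$mean_genes + .data$sd_genes),
      width = 0
    )
  }
  p + ggplot2::labs(x = paste0("Mean ", attr(x, "axis"), " per cell (bin center)"),
                    y = "Mean detected genes") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.saturation_curve <- function(object, ...) plot_saturation(object, ...)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
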