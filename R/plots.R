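#' ECDF overlays with per-organ curves
#'
#' One panel per gene: the pooled ECDF drawn in color over light grey ECDFs
#' of the individual organs, the standard view for judging organ-to-organ
#' scatter (per-organ curves are noisier because each organ contributes
#' fewer cells).
#'
#' @param cells Normalized cell table.
#' @param coordinate `"laminar"`, `"radial"` or `"z"`.
#' @param genes Genes to show (default: all present).
#' @return A ggplot object.
#' @export
plot_ecdfs <- function(cells, coordinate = "laminar", genes = NULL) {
  col <- coordinate_names[[match.arg(coordinate,
                                     names(coordinate_names))]]
  if (is.null(genes)) genes <- sort(unique(cells$gene))
  sub <- cells[cells$gene %in% genes & !is.na(cells[[col]]), ]
  sub$value <- sub[[col]]
  ggplot2::ggplot(sub, ggplot2::aes(x = .data$value)) +
    ggplot2::stat_ecdf(ggplot2::aes(group = .data$organ_id),
                       color = "grey80", linewidth = 0.3) +
    ggplot2::stat_ecdf(ggplot2::aes(color = .data$gene), linewidth = 0.7) +
    ggplot2::facet_wrap(~gene) +
    ggplot2::labs(x = paste("relative", coordinate, "position"),
                  y = "cumulative fraction of cells") +
    ggplot2::guides(color = "none") +
    ggplot2::theme_minimal()
}

#' Quartile-ellipse summary of joint gene positions
#'
#' Each gene is drawn as an ellipse centered on its medians and spanning Q1
#' to Q3 along both axes, condensing two coordinate distributions into one
#' comparison panel.
#'
#' @param descriptors Descriptor table from [summarize_distributions()].
#' @param x_coord,y_coord Coordinates for the axes.
#' @return A ggplot object.
#' @export
plot_quartile_ellipses <- function(descriptors, x_coord = "radial",
                                   y_coord = "laminar") {
  spec <- ellipse_specs(descriptors, x_coord, y_coord)
  theta <- seq(0, 2 * pi, length.out = 120)
  poly <- do.call(rbind, lapply(seq_len(nrow(spec)), function(i) {
    s <- spec[i, ]
    data.frame(gene = s$gene,
               x = s$x_center + (s$x_q3 - s$x_q1) / 2 * cos(theta),
               y = s$y_center + (s$y_q3 - s$y_q1) / 2 * sin(theta))
  }))
  ggplot2::ggplot(poly, ggplot2::aes(x = .data$x, y = .data$y,
                                     group = .data$gene,
                                     color = .data$gene)) +
    ggplot2::geom_path() +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = paste("relative", x_coord),
                  y = paste("relative", y_coord)) +
    ggplot2::theme_minimal()
}
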