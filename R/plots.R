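# Figure-style plots: recruitment heatmaps, stacked genus bars, pathway grids.

#' Plot a recruitment matrix
#'
#' Position-vs-identity heatmap with the colour scale normalised to the
#' largest bin; genome boundaries of multi-genome selections are drawn as
#' dashed verticals. An all-zero matrix renders axes without error.
#'
#' @param matrix a `recruitment_matrix` from [build_matrix()].
#' @param path optional output file (.png/.pdf/.svg inferred from the
#'   extension); when given the plot is written and the path returned.
#' @param title plot title.
#' @return The ggplot object (or `path`, invisibly, when writing).
#' @export
plot_recruitment <- function(matrix, path = NULL, title = "Fragment recruitment") {
  stopifnot(inherits(matrix, "recruitment_matrix"))
  idx <- which(matrix$counts > 0, arr.ind = TRUE)
  df <- if (nrow(idx)) {
    data.frame(pos = (matrix$pos_breaks[idx[, 1L]] +
                        matrix$pos_breaks[idx[, 1L] + 1L]) / 2 / 1000,
               identity = (matrix$id_breaks[idx[, 2L]] +
                             matrix$id_breaks[idx[, 2L] + 1L]) / 2,
               normalized = matrix$normalized[idx])
  } else {
    data.frame(pos = numeric(), identity = numeric(), normalized = numeric())
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$pos, .data$identity,
                                        colour = .data$normalized)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_viridis_c(limits = c(0, 1),
                                    name = "reads / max bin") +
    ggplot2::coord_cartesian(
      xlim = c(0, utils::tail(matrix$pos_breaks, 1L) / 1000),
      ylim = c(50, 100)) +
    ggplot2::labs(x = "position on concatenated reference [kbp]",
                  y = "read identity [%]", title = title) +
    ggplot2::theme_bw()
  if (length(matrix$offsets) > 1L)
    p <- p + ggplot2::geom_vline(xintercept = matrix$offsets[-1L] / 1000,
                                 linetype = "dashed", colour = "grey50")
  if (is.null(path)) return(p)
  ggplot2::ggsave(path, p, width = 7, height = 4, dpi = 150)
  invisible(path)
}

#' Stacked-bar plot of genus tables
#'
#' @param tables list of `genus_table` objects (one bar per sample).
#' @param path optional output file.
#' @return ggplot object (or `path`, invisibly).
#' @export
plot_genus_bars <- function(tables, path = NULL) {
  df <- do.call(rbind, lapply(tables, as.data.frame))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$sample, .data$percent,
                                        fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of all reads", fill = "category") +
    ggplot2::theme_bw()
  if (is.null(path)) return(p)
  ggplot2::ggsave(path, p, width = 6, height = 4, dpi = 150)
  invisible(path)
}

#' Coloured grid of pathway calls
#'
#' Green/yellow/gray/black cells for very likely / likely / unlikely / very
#' unlikely biosynthetic capability.
#'
#' @param calls data.frame from [score_matrix()].
#' @param path optional output file.
#' @return ggplot object (or `path`, invisibly).
#' @export
plot_pathway_matrix <- function(calls, path = NULL) {
  pal <- c(VERY_LIKELY = "#2e7d32", LIKELY = "#f9d51c",
           UNLIKELY = "#9e9e9e", VERY_UNLIKELY = "#212121")
  p <- ggplot2::ggplot(calls, ggplot2::aes(.data$pathway, .data$taxon,
                                           fill = .data$call)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = pal, drop = FALSE) +
    ggplot2::labs(x = NULL, y = NULL, fill = "biosynthesis") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (is.null(path)) return(p)
  ggplot2::ggsave(path, p, width = 6, height = 4, dpi = 150)
  invisible(path)
}
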