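#' Histogram of interquantile widths with the sharp/broad threshold
#'
#' @param shapes Tibble from [cluster_shape()].
#' @param sharp_max Sharp/broad threshold drawn and used for fill.
#' @return A ggplot object.
#' @export
plot_shape_distribution <- function(shapes, sharp_max = 10) {
  ggplot2::ggplot(shapes, ggplot2::aes(x = .data$iqr,
                                       fill = .data$iqr <= sharp_max)) +
    ggplot2::geom_histogram(binwidth = 2, boundary = 0, show.legend = TRUE) +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "#D55E00", `FALSE` = "#0072B2"),
      labels = c(`TRUE` = "sharp", `FALSE` = "broad"), name = NULL
    ) +
    ggplot2::labs(x = "interquantile width (bp)", y = "tag clusters") +
    ggplot2::theme_minimal()
}

#' Bar chart of cluster annotation categories
#'
#' @param annotated Tibble from [annotate_clusters()] (has a `category`
#'   column).
#' @return A ggplot object.
#' @export
plot_annotation_summary <- function(annotated) {
  ggplot2::ggplot(annotated, ggplot2::aes(y = .data$category)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "clusters", y = NULL) +
    ggplot2::theme_minimal()
}

#' Genome-browser style view of pooled signal in a region
#'
#' Plus-strand signal is drawn upward, minus-strand downward.
#'
#' @param pooled A pooled track.
#' @param chrom,from,to Region to draw (0-based half-open).
#' @return A ggplot object.
#' @export
plot_pooled_region <- function(pooled, chrom, from, to) {
  reg <- dplyr::filter(as_tibble(pooled), .data$chrom == .env$chrom,
                       .data$pos >= .env$from, .data$pos < .env$to)
  reg$y <- ifelse(reg$strand == "+", reg$score, -reg$score)
  ggplot2::ggplot(reg, ggplot2::aes(x = .data$pos, y = .data$y,
                                    fill = .data$strand)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c(`+` = "#0072B2", `-` = "#D55E00")) +
    ggplot2::labs(x = paste0(chrom, " position (bp)"),
                  y = "pooled signal (TPM)") +
    ggplot2::theme_minimal()
}
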