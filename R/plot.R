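## ggplot2 views of the main result types.

#' Expression heatmap across the sample design
#'
#' Tiles log2 expression for the requested rows over all samples in design
#' order (mitotic time course, YPD, YPA, SPII 1-12 h, starvation controls),
#' the standard way transcript-isoform induction patterns are displayed.
#'
#' @param expr An [expression_set()].
#' @param ids Row ids to display (default: all).
#' @return A ggplot.
#' @export
plot_expression_heatmap <- function(expr, ids = NULL) {
  values <- expr$values
  if (!is.null(ids)) values <- values[match(ids, values$id), ]
  long <- tidyr::pivot_longer(values, -"id", names_to = "sample", values_to = "log2")
  long$sample <- factor(long$sample, levels = expr$samples$id)
  long$id <- factor(long$id, levels = rev(values$id))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data$id,
                                     fill = .data$log2)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log2 signal") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       size = 6))
}

#' Length distributions of called mUTRs
#'
#' @param object A `mutr_calls` tibble.
#' @param ... Unused.
#' @return A ggplot of per-side length distributions with the mitotic
#'   reference medians (68 / 91 bp) marked.
#' @method autoplot mutr_calls
#' @export
autoplot.mutr_calls <- function(object, ...) {
  refs <- tibble(side = c("5p", "3p"), ref = c(68, 91))
  ggplot2::ggplot(object, ggplot2::aes(x = .data$side, y = .data$length)) +
    ggplot2::geom_boxplot(width = 0.5, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.5) +
    ggplot2::geom_point(data = refs, ggplot2::aes(y = .data$ref),
                        colour = "red", shape = 4, size = 3) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "mUTR length (bp)",
                  caption = "red cross: mitotic reference median") +
    ggplot2::theme_minimal()
}
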