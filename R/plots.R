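#' Volcano plot of a differential-expression table
#'
#' @param object A `circ_de` tibble from [de_test()].
#' @param ... Ignored.
#' @return A ggplot object (log2 fold change vs -log10 p, significant
#'   features coloured by direction).
#' @export
autoplot.circ_de <- function(object, ...) {
  df <- mutate(as_tibble(object),
               neg_log10_p = -log10(pmax(p_value, 1e-300)))
  ggplot2::ggplot(df, ggplot2::aes(x = log2fc, y = neg_log10_p,
                                   colour = direction)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b",
                                            down = "#27ae60",
                                            none = "grey60")) +
    ggplot2::labs(
      x = "log2 fold change (BOO / Sham)",
      y = expression(-log[10] ~ p),
      colour = NULL,
      title = sprintf("Differential expression (%s layer)",
                      attr(object, "layer") %||% "unspecified")
    ) +
    ggplot2::theme_minimal()
}

#' Plot the catalog summaries
#'
#' Three panels mirroring the standard catalog figures: mature-length
#' histogram, origin-class counts, and per-chromosome up/down counts of
#' significant events (when DE results were supplied to
#' [summarize_catalog()]).
#'
#' @param object A `circ_catalog_summary`.
#' @param which One of `"length"`, `"origin"`, `"chrom"`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.circ_catalog_summary <- function(object,
                                          which = c("length", "origin",
                                                    "chrom"), ...) {
  which <- match.arg(which)
  if (which == "length") {
    df <- object$length_histogram
    ggplot2::ggplot(df, ggplot2::aes(x = bin, y = count)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::labs(x = "mature circRNA length (nt)", y = "circRNAs") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                         vjust = 0.5,
                                                         hjust = 1))
  } else if (which == "origin") {
    ggplot2::ggplot(object$origin_counts,
                    ggplot2::aes(x = origin_class, y = count)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::labs(x = "genomic origin", y = "circRNAs") +
      ggplot2::theme_minimal()
  } else {
    df <- tidyr::pivot_longer(object$chrom_updown, c(up, down),
                              names_to = "direction", values_to = "count")
    ggplot2::ggplot(df, ggplot2::aes(x = chrom, y = count,
                                     fill = direction)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::scale_fill_manual(values = c(up = "#c0392b",
                                            down = "#27ae60")) +
      ggplot2::labs(x = NULL, y = "significant circRNAs", fill = NULL) +
      ggplot2::theme_minimal()
  }
}

#' Volcano plot shortcut
#'
#' @inheritParams autoplot.circ_de
#' @export
plot_volcano <- function(object, ...) autoplot.circ_de(object, ...)
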