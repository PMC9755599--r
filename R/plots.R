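#' Volcano plot of a differential-abundance result
#'
#' Cliff's delta effect size against -log10 q-value, significant features
#' highlighted.
#'
#' @param x A `qmp_diff` tibble from [differential_abundance()].
#' @param label_top Label the `label_top` most significant features
#'   (default 10).
#' @return A ggplot object.
#' @export
plot_volcano <- function(x, label_top = 10) {
  stopifnot(inherits(x, "qmp_diff"))
  dat <- x |> filter(!.data$untestable)
  lab <- dat |> arrange(.data$q_value) |> head(label_top) |>
    filter(.data$significant)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$cliffs_delta,
                                    y = -log10(.data$q_value))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant),
                        alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(attr(x, "fdr")),
                        linetype = "dashed", colour = "red") +
    ggplot2::geom_text(data = lab, ggplot2::aes(label = .data$feature),
                       size = 2.5, vjust = -0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "Cliff's delta", y = expression(-log[10]~q),
                  colour = "significant") +
    ggplot2::theme_minimal()
}

#' Ordination plot of a PCoA result
#'
#' @param x A `qmp_pcoa` from [pcoa_ordination()].
#' @param metadata Optional tibble with `sample_id` and a grouping column.
#' @param colour Name of the metadata column to colour by.
#' @return A ggplot object.
#' @export
plot_ordination <- function(x, metadata = NULL, colour = "group") {
  stopifnot(inherits(x, "qmp_pcoa"))
  dat <- x$coordinates
  if (!is.null(metadata)) {
    dat <- left_join(dat, metadata, by = "sample_id")
  }
  ve <- sprintf("%.1f%%", 100 * x$variance_explained[1:2])
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  if (!is.null(metadata) && colour %in% names(dat)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]))
  } else {
    p <- p + ggplot2::geom_point()
  }
  p + ggplot2::labs(x = paste0("PC1 (", ve[1], ")"),
                    y = paste0("PC2 (", ve[2], ")")) +
    ggplot2::theme_minimal()
}

#' @rdname plot_ordination
#' @param object A `qmp_pcoa`.
#' @param ... Passed to [plot_ordination()].
#' @export
autoplot.qmp_pcoa <- function(object, ...) plot_ordination(object, ...)

#' @rdname plot_volcano
#' @param object A `qmp_diff`.
#' @param ... Passed to [plot_volcano()].
#' @export
autoplot.qmp_diff <- function(object, ...) plot_volcano(object, ...)
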