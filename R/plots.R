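# ggplot2 views of the main result types. Plots are a convenience layer;
# every number they display comes from the tables they are built on.

#' Volcano plot of a moderated fit
#'
#' @param object A `moderated_fit`.
#' @param alpha,fc_cut Thresholds drawn as guide lines and used to colour
#'   the calls.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot moderated_fit
#' @export
autoplot.moderated_fit <- function(object, alpha = 0.05, fc_cut = 2, ...) {
  d <- object$table |>
    mutate(call = case_when(
      .data$adj_p < alpha & .data$log2fc >= log2(fc_cut) ~ "up",
      .data$adj_p < alpha & .data$log2fc <= -log2(fc_cut) ~ "down",
      TRUE ~ "ns"
    ))
  ggplot2::ggplot(d, ggplot2::aes(.data$log2fc, -log10(.data$adj_p),
                                  colour = .data$call)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::geom_vline(xintercept = c(-log2(fc_cut), log2(fc_cut)),
                        linetype = 2) +
    ggplot2::scale_colour_manual(
      values = c(up = "#c0392b", down = "#2980b9", ns = "grey60")
    ) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p",
                  colour = NULL,
                  title = sprintf("%s vs %s", object$case, object$ref)) +
    ggplot2::theme_minimal()
}

#' Histogram and fitted Gaussian of log10 fold enrichment
#'
#' @param object An `fe_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fe_fit
#' @export
autoplot.fe_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$mid, .data$count)) +
    ggplot2::geom_col(fill = "grey75", width = diff(d$mid[1:2]) * 0.95) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "#c0392b",
                       linewidth = 0.8) +
    ggplot2::labs(x = "log10 fold enrichment", y = "peak count",
                  title = sprintf("area = %.1f, sd = %.4f",
                                  object$area, object$sd)) +
    ggplot2::theme_minimal()
}

#' Sample scores of a filtered PCA
#'
#' @param object An `ac4c_pca`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ac4c_pca
#' @export
autoplot.ac4c_pca <- function(object, ...) {
  ve <- object$var_explained
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(.data$PC1, .data$PC2, colour = .data$group)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * ve[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * ve[2])
    ) +
    ggplot2::theme_minimal()
}

#' Bar chart of detection-class counts per omics layer
#'
#' @param result An `ac4c_result`.
#' @return A ggplot object.
#' @export
plot_venn_counts <- function(result) {
  d <- purrr::imap_dfr(result$integration$venn_counts, function(v, nm) {
    tibble(layer = nm, class = factor(names(v), VENN_LEVELS),
           count = as.integer(v))
  })
  ggplot2::ggplot(d, ggplot2::aes(.data$class, .data$count,
                                  fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~layer, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "features", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
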