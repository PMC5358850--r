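#' Bar plot of per-gene mean delta-Ct by lymph-node status
#'
#' @param dct Long delta-Ct tibble.
#' @param annotation Annotation tibble (`sample_id`, `ln_status`).
#' @return A ggplot object.
#' @export
plot_gene_means <- function(dct, annotation) {
  gm <- gene_group_means(dct, annotation)
  ggplot2::ggplot(gm, ggplot2::aes(x = .data$gene, y = .data$mean_delta_ct,
                                   fill = .data$ln_status)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = expression(paste("Mean ", Delta, "Ct")),
                  fill = "LN status") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Jittered distribution plot of delta-Ct per gene and group
#'
#' A beeswarm-style summary: per-gene jittered points split by LN status
#' with boxplot quartiles overlaid.
#'
#' @param dct Long delta-Ct tibble.
#' @param annotation Annotation tibble (`sample_id`, `ln_status`).
#' @param genes Genes to show (default: all).
#' @return A ggplot object.
#' @export
plot_delta_ct_distribution <- function(dct, annotation, genes = NULL) {
  d <- dct |>
    dplyr::inner_join(dplyr::select(annotation, "sample_id", "ln_status"),
                      by = "sample_id") |>
    dplyr::filter(!is.na(.data$delta_ct), !is.na(.data$ln_status))
  if (!is.null(genes)) d <- dplyr::filter(d, .data$gene %in% genes)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ln_status, y = .data$delta_ct)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::facet_wrap(~gene, scales = "free_y") +
    ggplot2::labs(x = NULL, y = expression(paste(Delta, "Ct"))) +
    ggplot2::theme_minimal()
}
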