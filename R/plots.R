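# ggplot2 displays for the main result types.

#' Plot RT profiles in a genomic region
#'
#' Replicate traces colored by condition; positive RT = early
#' replication.
#'
#' @param profiles long RT profile tibble.
#' @param chrom,start,end region to display.
#' @return A ggplot.
#' @export
plot_rt_profile <- function(profiles, chrom, start = 0, end = Inf) {
  sub <- profiles %>%
    filter(.data$chrom == !!chrom, .data$start >= !!start,
           .data$end <= !!end)
  ggplot2::ggplot(sub, ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                                    y = .data$rt, group = .data$sample,
                                    color = .data$condition)) +
    ggplot2::geom_line(alpha = 0.7, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::labs(x = sprintf("%s position (Mb)", chrom),
                  y = "RT  log2(early/late)", color = NULL) +
    ggplot2::theme_minimal()
}

#' PCA projection of RT profiles
#'
#' @param x an `rt_correlation` object ([correlate_profiles()]).
#' @return A ggplot of samples on the first two principal components.
#' @export
autoplot_rt_pca <- function(x) {
  ggplot2::ggplot(x$scores,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               color = .data$condition,
                               label = .data$sample)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(vjust = -1, show.legend = FALSE, size = 3) +
    ggplot2::labs(color = NULL) +
    ggplot2::theme_minimal()
}

#' Metagene heat map
#'
#' Genes (rows, sorted largest to smallest) by stretched gene-body and
#' flank columns.
#'
#' @param x a `metagene_matrix` object.
#' @return A ggplot.
#' @export
autoplot_metagene <- function(x) {
  df <- as_tibble(x$matrix, rownames = "gene_id", .name_repair = "minimal")
  names(df)[-1] <- as.character(seq_len(ncol(x$matrix)))
  df <- df %>%
    mutate(row = dplyr::row_number()) %>%
    pivot_longer(-c("gene_id", "row"), names_to = "column",
                 values_to = "value") %>%
    mutate(column = as.integer(.data$column))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$column, y = -.data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::geom_vline(xintercept = range(x$body_cols) + c(-0.5, 0.5),
                        linewidth = 0.3) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", midpoint = 0,
                                  na.value = "grey90") +
    ggplot2::labs(x = "flank | stretched gene body | flank", y = NULL,
                  fill = "RT") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Plot a V-shape call over a gene
#'
#' @param delta_track delta tibble over the searched span.
#' @param vres one-row result of [detect_v_shape()].
#' @param gene one-row gene table.
#' @return A ggplot with the gene body, vertex and CFR marked.
#' @export
plot_v_shape <- function(delta_track, vres, gene) {
  ggplot2::ggplot(delta_track,
                  ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                               y = .data$delta)) +
    ggplot2::annotate("rect", xmin = gene$start / 1e6, xmax = gene$end / 1e6,
                      ymin = -Inf, ymax = Inf, alpha = 0.1, fill = "grey40") +
    {if (isTRUE(vres$is_v))
      ggplot2::annotate("rect", xmin = vres$cfr_start / 1e6,
                        xmax = vres$cfr_end / 1e6, ymin = -Inf, ymax = Inf,
                        alpha = 0.2, fill = "gold")} +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = vres$vertex / 1e6, linetype = 2,
                        color = "red") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = sprintf("%s position (Mb)", gene$chrom),
                  y = expression(Delta * "RT (APH - control)")) +
    ggplot2::theme_minimal()
}

#' Null distribution of a shuffle-enrichment test
#'
#' @param x an `enrichment_result`.
#' @return A ggplot: null histogram with the observed count marked.
#' @export
autoplot_enrichment <- function(x) {
  ggplot2::ggplot(tidy(x), ggplot2::aes(x = .data$null_overlap)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70") +
    ggplot2::geom_vline(xintercept = x$observed, color = "red") +
    ggplot2::labs(x = "boundaries overlapping peaks (null)", y = "count",
                  subtitle = sprintf("observed = %d, fold = %.2f, p = %.3g",
                                     x$observed, x$fold, x$p_value)) +
    ggplot2::theme_minimal()
}
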