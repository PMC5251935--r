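#' Plot a consensus matrix as a heatmap
#'
#' Samples are ordered by their consensus cluster; a clean k-subpopulation
#' structure shows as k bright diagonal blocks.
#'
#' @param object An `nmf_consensus`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nmf_consensus <- function(object, ...) {
  ord <- names(sort(object$labels))
  df <- tibble::as_tibble(object$consensus, rownames = "sample_a") |>
    tidyr::pivot_longer(-"sample_a", names_to = "sample_b",
                        values_to = "consensus") |>
    dplyr::mutate(sample_a = factor(.data$sample_a, levels = ord),
                  sample_b = factor(.data$sample_b, levels = ord))
  ggplot2::ggplot(df, ggplot2::aes(.data$sample_a, .data$sample_b,
                                   fill = .data$consensus)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Consensus matrix (k = %d, %d runs)",
                                  object$k, object$n_runs)) +
    ggplot2::theme(axis.text = ggplot2::element_blank(),
                   axis.ticks = ggplot2::element_blank())
}

#' Plot cophenetic correlation against candidate rank
#'
#' @param object An `nmf_rank_selection`.
#' @param ... Unused.
#' @return A ggplot; the chosen rank is highlighted.
#' @export
autoplot.nmf_rank_selection <- function(object, ...) {
  df <- object$cophenetic
  ggplot2::ggplot(df, ggplot2::aes(.data$k, .data$cophenetic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$k == object$best_k),
                        size = 3, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red")) +
    ggplot2::scale_x_continuous(breaks = df$k) +
    ggplot2::labs(x = "rank k", y = "cophenetic correlation",
                  title = sprintf("Rank selection (best k = %d)", object$best_k))
}

#' MA-style plot of D-scores over mean expression
#'
#' Shows which expression regime the feature genes occupy: D-score selects
#' genes of intermediate absolute expression, because loadings scale with
#' expression level and uniformly high genes cancel in the score.
#'
#' @param dscores Tibble from [rank_genes()].
#' @param m The expression matrix the factorization was fitted to.
#' @return A ggplot of log2 mean expression vs D-score, feature genes
#'   highlighted.
#' @export
plot_dscore <- function(dscores, m) {
  df <- dplyr::mutate(dscores,
                      mean_expr = rowMeans(m)[dscores$gene_id])
  ggplot2::ggplot(df, ggplot2::aes(log2(.data$mean_expr + 1),
                                   .data$d_score,
                                   colour = .data$is_feature)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "blue")) +
    ggplot2::labs(x = "log2(mean expression + 1)", y = "D-score",
                  colour = "feature gene")
}

#' Bar plot of a clustering benchmark
#'
#' @param object Tibble from [benchmark_clustering()].
#' @return A ggplot: mean Rand measure per method with standard-deviation
#'   error bars; asterisks mark methods significantly worse than the NMF
#'   reference arm.
#' @export
plot_benchmark <- function(object) {
  df <- dplyr::mutate(object,
                      arm = ifelse(.data$tsne, "with t-SNE", "no t-SNE"),
                      label = ifelse(.data$significantly_worse, "*", ""))
  ggplot2::ggplot(df, ggplot2::aes(.data$method, .data$mean_rand,
                                   fill = .data$arm)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_rand - .data$sd_rand,
                                        ymax = .data$mean_rand + .data$sd_rand),
                           position = "dodge") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label,
                                    y = .data$mean_rand + .data$sd_rand + 0.02),
                       position = ggplot2::position_dodge(width = 0.9)) +
    ggplot2::labs(x = NULL, y = "Rand measure", fill = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
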