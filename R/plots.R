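# ggplot2 displays for the main result types.

#' Volcano plot of the three DE scorers
#'
#' @param object a `sciq_de` tibble from [run_de_suite()].
#' @param t [thresholds()] drawn as guide lines and used to colour calls.
#' @param ... unused.
#' @return a ggplot object (one facet per scorer).
#' @export
autoplot.sciq_de <- function(object, t = thresholds(), ...) {
  df <- dplyr::mutate(
    object,
    significant = .data$padj <= t$padj_max &
      abs(.data$log2FC) >= t$abs_log2fc_min
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2FC,
                                   y = -log10(pmax(.data$padj, 1e-300)),
                                   colour = .data$significant)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * t$abs_log2fc_min,
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = -log10(t$padj_max),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::facet_wrap(~method_id) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change (injured / control)",
                  y = expression(-log[10] ~ P[adj]),
                  colour = "passes thresholds")
}

#' Bar chart of significant categories
#'
#' The -log10 Bonferroni-corrected p-value per significant category,
#' over- and underrepresentation shown as filled and open bars.
#'
#' @param object tibble from [significant_categories()].
#' @param alpha significance level drawn as a dashed guide (default 0.05).
#' @param ... unused.
#' @return a ggplot object.
#' @export
plot_overrepresentation <- function(object, alpha = 0.05, ...) {
  df <- dplyr::mutate(
    object,
    category_id = stats::reorder(.data$category_id, .data$neg_log10_p_bonf))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category_id,
                                   y = .data$neg_log10_p_bonf,
                                   fill = .data$direction)) +
    ggplot2::geom_col(colour = "black", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c(over = "black", under = "white")) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(-log[10] ~ "corrected p"))
}

#' Cell-type percentage heatmap
#'
#' Percentage-of-sum profiles as a tile map, rows ordered by the clustering
#' when one is supplied.
#'
#' @param object a `sciq_profiles` tibble from [percentage_profile()].
#' @param clustering optional `sciq_clustering` from [cluster_profiles()]
#'   supplying the row order.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.sciq_profiles <- function(object, clustering = NULL, ...) {
  ct <- celltype_cols(object)
  long <- tidyr::pivot_longer(object[, c("gene_id", ct)], -"gene_id",
                              names_to = "cell_type",
                              values_to = "percentage")
  order <- if (!is.null(clustering)) {
    rev(clustering$ordering$gene_id)
  } else {
    rev(sort(unique(long$gene_id)))
  }
  long$gene_id <- factor(long$gene_id, levels = order)
  long$cell_type <- factor(long$cell_type, levels = ct)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cell_type, y = .data$gene_id,
                                     fill = .data$percentage)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 100)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "% of summed\nexpression") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Candidate-gene profile heatmap
#'
#' Row-relative expression of the candidate list across groups, with injury
#' significance marked `*` and development significance marked `#`.
#'
#' @param object a `sciq_profile_table` from [build_profile_table()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.sciq_profile_table <- function(object, ...) {
  long <- tidy(object)
  long$mark <- paste0(ifelse(long$injury_flag, "*", ""),
                      ifelse(long$development_flag, "#", ""))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$gene_id,
                                     fill = .data$scaled)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$mark), size = 3) +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick", midpoint = 0.5) +
    ggplot2::labs(x = NULL, y = NULL, fill = "relative\nexpression")
}
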