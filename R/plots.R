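## ggplot2 autoplot() methods for the result classes.

.direction_scale <- function() {
  ggplot2::scale_colour_manual(
    values = c(UP = "#c0392b", DOWN = "#2e6fb7", UNDEFINED = "grey60"),
    drop = TRUE)
}

#' Plot per-cohort permutation results
#'
#' Pathway mean-t score against permutation significance, coloured by
#' direction, with a dashed line at the requested significance level.
#'
#' @param object A `pathway_perm_result` tibble.
#' @param alpha Reference significance level drawn on the plot.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot pathway_perm_result
#' @export
autoplot.pathway_perm_result <- function(object, alpha = 0.05, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$score, y = -log10(.data$p_perm),
                               colour = .data$direction)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    .direction_scale() +
    ggplot2::labs(x = "pathway score (mean t)",
                  y = expression(-log[10] ~ "permutation p"),
                  colour = "direction",
                  title = attr(object, "dataset_id")) +
    ggplot2::theme_minimal()
}

#' Volcano-style plot of the gene-level meta-analysis
#'
#' @param object A `meta_gene_result` tibble.
#' @param alpha Reference combined-p level drawn on the plot.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot meta_gene_result
#' @export
autoplot.meta_gene_result <- function(object, alpha = 0.05, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$mean_t, y = -log10(.data$p_combined),
                               colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    .direction_scale() +
    ggplot2::labs(x = "mean t across cohorts",
                  y = expression(-log[10] ~ "combined p"),
                  colour = "direction") +
    ggplot2::theme_minimal()
}

#' Dot plot of pathway over-representation
#'
#' @param object An `enrichment_result` tibble (directions optional).
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$pathway <- stats::reorder(paste(df$pathway_id, df$name), -df$p_enrich)
  if (is.null(df$direction)) df$direction <- "UNDEFINED"
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$p_enrich),
                                   y = .data$pathway,
                                   size = .data$n_overlap,
                                   colour = .data$direction)) +
    ggplot2::geom_point() +
    .direction_scale() +
    ggplot2::labs(x = expression(-log[10] ~ "enrichment p"), y = NULL,
                  size = "genes in overlap", colour = "direction") +
    ggplot2::theme_minimal()
}

#' Bar chart of the consensus report
#'
#' @param object A `consensus_result` tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot consensus_result
#' @export
autoplot.consensus_result <- function(object, ...) {
  df <- build_report(object)
  df$pathway <- stats::reorder(paste(df$pathway_id, df$name), df$n_key_genes)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_key_genes, y = .data$pathway,
                                   fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(
      values = c(UP = "#c0392b", DOWN = "#2e6fb7", UNDEFINED = "grey60")) +
    ggplot2::labs(x = "key genes (combined p < 0.05)", y = NULL,
                  fill = "direction") +
    ggplot2::theme_minimal()
}
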